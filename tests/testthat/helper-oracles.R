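# Independent oracles, deliberately written as direct restatements of the
# rules rather than reusing any package internals.

# brute-force per-nucleus classifier: literal case analysis
bruteClassify <- function(nRed, nGreen, monosomyRule) {
  if (nRed == 2 && nGreen == 2) return("NORMAL")
  if (nRed == 1 && nGreen == 1)
    return(if (monosomyRule) "MONOSOMY" else "UNINFORMATIVE")
  if (nGreen == 0) return("UNINFORMATIVE")
  if (nRed == 0) return("UNINFORMATIVE")
  r <- nRed / nGreen
  if (r <= 0.5 && nGreen >= 2) return("TARGET_DELETED")
  if (r > 0.5 && max(nRed, nGreen) >= 3) return("POLYSOMY_IMBALANCED")
  "UNINFORMATIVE"
}

# Cohen's kappa straight from the confusion matrix
kappaFromMatrix <- function(m) {
  n <- sum(m)
  po <- sum(diag(m)) / n
  pe <- sum(rowSums(m) * colSums(m)) / n^2
  (po - pe) / (1 - pe)
}

# expand a confusion matrix into paired manual/automated vectors
pairsFromMatrix <- function(m, labels = rownames(m)) {
  man <- character(0); aut <- character(0)
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    man <- c(man, rep(labels[i], m[i, j]))
    aut <- c(aut, rep(labels[j], m[i, j]))
  }
  data.frame(manual = man, automated = aut, stringsAsFactors = FALSE)
}
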
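# Independent brute-force oracles, written straight from the definitions
# and never touching package internals.

# per-class metrics by looping over observations
brute_metrics <- function(y_true, y_pred, classes) {
  K <- length(classes)
  acc <- mean(y_true == y_pred)
  sens <- spec <- prec <- numeric(K)
  for (j in seq_len(K)) {
    cl <- classes[j]
    tp <- sum(y_true == cl & y_pred == cl)
    fn <- sum(y_true == cl & y_pred != cl)
    fp <- sum(y_true != cl & y_pred == cl)
    tn <- sum(y_true != cl & y_pred != cl)
    sens[j] <- if (tp + fn > 0) tp / (tp + fn) else NA
    spec[j] <- if (tn + fp > 0) tn / (tn + fp) else NA
    prec[j] <- if (tp + fp > 0) tp / (tp + fp) else NA
  }
  pe <- 0
  for (j in seq_len(K))
    pe <- pe + mean(y_true == classes[j]) * mean(y_pred == classes[j])
  list(accuracy = acc, sensitivity = sens, specificity = spec,
       precision = prec, f_score = 2 * prec * sens / (prec + sens),
       kappa = (acc - pe) / (1 - pe))
}

# AUC as exhaustive pairwise concordance probability (ties count half)
concordance_auc <- function(y, s) {
  pos <- which(y == 1); neg <- which(y == 0)
  tot <- 0
  for (i in pos) for (j in neg)
    tot <- tot + (s[i] > s[j]) + 0.5 * (s[i] == s[j])
  tot / (length(pos) * length(neg))
}
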
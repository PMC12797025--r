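# Shared fixtures, built in code. The memoized study dataset keeps the
# expensive generation out of every test block that needs one.

.fixture_env <- new.env(parent = emptyenv())

fixture_study <- function(seed = 42L, n = 315L) {
  key <- paste0("study_", seed, "_", n)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- make_study_dataset(synthetic_config(
      n_compounds = n, seed = seed))
  }
  .fixture_env[[key]]
}

# raw fingerprint from explicit bit positions (1-based), for exact-value tests
fp_from_bits <- function(positions, n_bits = 16L) {
  bits <- integer(n_bits)
  bits[positions] <- 1L
  structure(bits, popcount = sum(bits), n_bits = n_bits, class = "fingerprint")
}

# independent brute-force Tanimoto: explicit loop over positions
tanimoto_bruteforce <- function(a, b) {
  inter <- 0L; uni <- 0L
  for (i in seq_along(a)) {
    ai <- a[i] != 0; bi <- b[i] != 0
    if (ai && bi) inter <- inter + 1L
    if (ai || bi) uni <- uni + 1L
  }
  if (uni == 0L) 0 else inter / uni
}

# independent confusion-matrix oracle for binary reports
report_oracle <- function(y_true, y_pred) {
  out <- list()
  for (cl in c("non-binder", "binder")) {
    tp <- sum(y_true == cl & y_pred == cl)
    fp <- sum(y_true != cl & y_pred == cl)
    fn <- sum(y_true == cl & y_pred != cl)
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    out[[cl]] <- c(precision = prec, recall = rec, f1 = f1,
                   support = sum(y_true == cl))
  }
  n <- length(y_true)
  w <- c(out[["non-binder"]][["support"]], out[["binder"]][["support"]]) / n
  list(per_class = out,
       accuracy = mean(y_true == y_pred),
       macro_f1 = mean(c(out[["non-binder"]][["f1"]], out[["binder"]][["f1"]])),
       weighted_f1 = sum(w * c(out[["non-binder"]][["f1"]],
                               out[["binder"]][["f1"]])))
}
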
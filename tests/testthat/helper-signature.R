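# Class-labelled expression benchmark for the AUC-RF stage: n_informative
# genes shifted by `shift` SD in the Poor class among pure-noise candidates.
make_rf_bench <- function(seed, n = 40L, p = 59L, n_informative = 5L,
                          shift = 2) {
  set.seed(seed + 5000L)
  cls <- rep(c("Poor", "Good"), each = n / 2)
  x <- matrix(rnorm(p * n), p, n,
              dimnames = list(sprintf("c%02d", seq_len(p)),
                              sprintf("s%02d", seq_len(n))))
  if (n_informative > 0L) {
    x[seq_len(n_informative), cls == "Poor"] <-
      x[seq_len(n_informative), cls == "Poor"] + shift
  }
  list(
    x = x,
    labels = data.frame(sample_id = colnames(x), class = cls),
    informative = rownames(x)[seq_len(n_informative)]
  )
}
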
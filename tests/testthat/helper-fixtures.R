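# Fixtures built in code. The planted-signal world: five arms whose ADAS-cog
# drifts span 4 points, trajectory noise sd 2, AR(1) coupling 0.5 —
# a cohort in which treatment assignment and the observed 3-month course
# genuinely predict 6-month conversion.

planted_spec <- function(n = 600, seed = 7, noise_sd = 2, ar1 = 0.5) {
  cohort_spec(
    n_patients = n,
    drift = c(observation = 1, exercise = -1, donepezil = -3,
              gbe = -3, donepezil_gbe = -2),
    noise_sd = noise_sd, ar1 = ar1, miss_rate = 0, seed = seed
  )
}

# Minimal hand-built cohort-like table (no schema attribute): two features,
# three visits per patient.
tiny_table <- function(adas_by_visit, extra = NULL) {
  n <- nrow(adas_by_visit)
  out <- do.call(rbind, lapply(seq_len(ncol(adas_by_visit)), function(v) {
    data.frame(id = seq_len(n), month = c(0, 3, 6)[v],
               diagnosis = "AD",
               adas_cog = adas_by_visit[, v])
  }))
  if (!is.null(extra)) out <- cbind(out, extra[rep(seq_len(n), 3), , drop = FALSE])
  out[order(out$id, out$month), ]
}

# Independent forward oracle for the static encoder: plain loops, no reuse of
# package internals beyond the weight list itself.
encoder_oracle <- function(x, params) {
  a <- x
  for (l in 1:5) {
    z <- as.numeric(a %*% params$enc$W[[l]]) + as.numeric(params$enc$b[[l]])
    a <- ifelse(z > 0, z, 0)
  }
  g <- sum(a * params$score$W) + as.numeric(params$score$b)
  1 / (1 + exp(-g))
}

# Brute-force pairwise-concordance AUC oracle.
auc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}
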
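# Independent oracles and fixture builders shared across test files.

# Brute-force Mann-Whitney AUC: enumerate every positive-negative pair,
# ties counted 1/2. Quadratic on purpose — the oracle must not share code
# with the rank-based implementation it checks.
auc_enum <- function(scores, labels) {
  y <- as.logical(labels)
  pos <- scores[y]; neg <- scores[!y]
  tot <- 0
  for (x in pos) for (z in neg)
    tot <- tot + if (x > z) 1 else if (x == z) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# Stratified bootstrap SE of a paired AUC difference.
boot_se_dauc <- function(scores_a, scores_b, labels, n_boot = 2000, seed = 1) {
  y <- as.logical(labels)
  ip <- which(y); im <- which(!y)
  set.seed(seed)
  d <- replicate(n_boot, {
    idx <- c(sample(ip, replace = TRUE), sample(im, replace = TRUE))
    auc_mw(scores_a[idx], y[idx]) - auc_mw(scores_b[idx], y[idx])
  })
  sd(d)
}

# Assemble a power_spectrum object directly from a matrix fixture.
make_spectrum <- function(power, freqs, labels) {
  power <- matrix(power, nrow = length(labels), ncol = length(freqs),
                  dimnames = list(labels, NULL))
  structure(list(freqs = freqs, power = power,
                 resolution = if (length(freqs) > 1) diff(freqs)[1] else 1,
                 n_epochs = 1, channel_labels = labels, meta = list()),
            class = "power_spectrum")
}

# Cohort with binary variables hitting exact case counts per outcome group.
exact_count_cohort <- function(counts) {
  # counts: named list of c(events_survivor, n_survivor, events_nonsurv, n_nonsurv)
  ns <- counts[[1]][2]; nn <- counts[[1]][4]
  df <- data.frame(id = seq_len(ns + nn),
                   died90 = rep(c(FALSE, TRUE), c(ns, nn)))
  for (nm in names(counts)) {
    v <- counts[[nm]]
    df[[nm]] <- c(rep(c(TRUE, FALSE), c(v[1], v[2] - v[1])),
                  rep(c(TRUE, FALSE), c(v[3], v[4] - v[3])))
  }
  df
}

table2_fractions <- function() {
  c(delta = 0.744, theta = 0.084, alpha = 0.095, beta = 0.064) / 0.987
}
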
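# Independent brute-force oracles and small fixture builders. The oracles
# deliberately use naive O(n*m) scans / full enumeration so they share no
# code with the implementation they check.

make_series <- function(t, hr, subject = "S01", device = "dev") {
  tibble::tibble(
    subject_id = subject, device_id = device, t_s = t, hr_bpm = hr
  )
}

random_series <- function(n, t_max = 2000, subject = "S01", device = "dev") {
  t <- sort(sample(0:t_max, n))
  make_series(t, runif(n, 60, 160), subject = subject, device = device)
}

# naive per-second pairing: scan every (ref, dev) sample pair
brute_per_second <- function(ref, dev) {
  out <- list()
  for (i in seq_len(nrow(ref))) {
    for (j in seq_len(nrow(dev))) {
      if (ref$subject_id[i] == dev$subject_id[j] &&
        floor(ref$t_s[i]) == floor(dev$t_s[j])) {
        out[[length(out) + 1]] <- data.frame(
          subject_id = ref$subject_id[i], t_s = floor(ref$t_s[i]),
          ref_bpm = ref$hr_bpm[i], dev_bpm = dev$hr_bpm[j]
        )
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(
      subject_id = character(0), t_s = numeric(0),
      ref_bpm = numeric(0), dev_bpm = numeric(0)
    ))
  }
  df <- do.call(rbind, out)
  df[order(df$subject_id, df$t_s), , drop = FALSE]
}

# naive trailing-window pairing: for every ref timestamp scan all dev samples
brute_trailing <- function(ref, dev, window) {
  out <- list()
  for (i in seq_len(nrow(ref))) {
    t <- ref$t_s[i]
    sel <- dev$subject_id == ref$subject_id[i] &
      dev$t_s > t - window & dev$t_s <= t
    if (any(sel)) {
      out[[length(out) + 1]] <- data.frame(
        subject_id = ref$subject_id[i], t_s = t,
        ref_bpm = ref$hr_bpm[i], dev_bpm = mean(dev$hr_bpm[sel])
      )
    }
  }
  if (length(out) == 0) {
    return(data.frame(
      subject_id = character(0), t_s = numeric(0),
      ref_bpm = numeric(0), dev_bpm = numeric(0)
    ))
  }
  df <- do.call(rbind, out)
  df[order(df$subject_id, df$t_s), , drop = FALSE]
}

# naive synchronized-bin pairing
brute_sync <- function(ref, dev, window) {
  out <- list()
  for (s in unique(ref$subject_id)) {
    r <- ref[ref$subject_id == s, ]
    d <- dev[dev$subject_id == s, ]
    for (k in unique(floor(r$t_s / window))) {
      rsel <- floor(r$t_s / window) == k
      dsel <- floor(d$t_s / window) == k
      if (any(rsel) && any(dsel)) {
        out[[length(out) + 1]] <- data.frame(
          subject_id = s, t_s = k * window,
          ref_bpm = mean(r$hr_bpm[rsel]), dev_bpm = mean(d$hr_bpm[dsel])
        )
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(
      subject_id = character(0), t_s = numeric(0),
      ref_bpm = numeric(0), dev_bpm = numeric(0)
    ))
  }
  df <- do.call(rbind, out)
  df[order(df$subject_id, df$t_s), , drop = FALSE]
}

expect_pairs_equal <- function(pd, oracle) {
  pd <- as.data.frame(pd)[, c("subject_id", "t_s", "ref_bpm", "dev_bpm")]
  rownames(pd) <- NULL
  rownames(oracle) <- NULL
  expect_equal(nrow(pd), nrow(oracle))
  expect_equal(pd$t_s, oracle$t_s)
  expect_equal(pd$ref_bpm, oracle$ref_bpm)
  expect_equal(pd$dev_bpm, oracle$dev_bpm, tolerance = 1e-10)
}

# exact two-sided signed-rank p-value by enumeration of all 2^n sign vectors
enumerate_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  # two-sided: double the smaller tail (distribution symmetric about n(n+1)/4)
  mu <- n * (n + 1) / 4
  p <- 2 * min(mean(w_all <= w_obs), mean(w_all >= w_obs))
  min(p, 1)
}

# a small paired dataset with a known error structure
toy_paired <- function(n_subjects = 6, n_per = 30, bias = 0, sd = 3,
                       seed = 1) {
  set.seed(seed)
  dplyr::bind_rows(lapply(seq_len(n_subjects), function(i) {
    ref <- runif(n_per, 70, 150)
    tibble::tibble(
      subject_id = sprintf("S%02d", i),
      t_s = seq_len(n_per),
      ref_bpm = ref,
      dev_bpm = ref + bias + rnorm(n_per, 0, sd)
    )
  }))
}

# flat-trajectory cohort: same load in every phase, no orthostatic pulse,
# so steady and transition timestamps are exchangeable under equal noise
flat_protocol <- function() {
  hr_protocol(tibble::tibble(
    name = paste0("p", 1:6),
    duration_s = c(180, 180, 240, 240, 240, 120),
    load = factor(rep("sit", 6), levels = "sit", ordered = TRUE)
  ))
}
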
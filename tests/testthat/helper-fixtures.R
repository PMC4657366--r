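# Fixture builders shared across test files.

# A reference fundus/vessel rendering plus a target warped by a known
# ground-truth transform (with mild independent intensity noise).
mk_registration_pair <- function(seed, size = 256, truth = NULL,
                                 noise_sd = 2) {
  vm <- generate_vessel_tree(vessel_tree_spec(seed = seed), size)
  fd <- generate_fundus(vm, seed + 1000)
  if (is.null(truth)) {
    set.seed(seed + 2000)
    truth <- similarity_transform(rnorm(1, 0, 5), rnorm(1, 0, 5),
                                  rnorm(1, 0, 3), exp(rnorm(1, 0, 0.02)))
  }
  tgt_f <- apply_transform(fd, truth)
  if (noise_sd > 0) {
    set.seed(seed + 3000)
    tgt_f$pixels <- pmin(pmax(tgt_f$pixels +
      matrix(rnorm(size^2, 0, noise_sd), size, size) * tgt_f$valid_mask, 0), 255)
  }
  list(ref_fundus = fd, ref_vessels = vm, tgt_fundus = tgt_f,
       tgt_vessels = apply_transform(vm, truth), truth = truth)
}

# Recovery error of an estimated correction against the ground truth:
# compose(correction, truth) should be the identity.
recovery_error <- function(correction, truth) {
  e <- compose_transforms(correction, truth)
  c(tx = abs(e$tx_px), ty = abs(e$ty_px), rot = abs(e$rotation_deg),
    scale = abs(e$scale - 1))
}

# Simulated trend-model table at the published study design.
mk_trend_table <- function(seed, slope = 0, b_sd = 5, e_sd = 3,
                           sessions = c(8, 16, 16), total_days = 210) {
  set.seed(seed)
  rows <- lapply(seq_along(sessions), function(s) {
    n <- sessions[s]
    days <- c(0, sort(sample(seq_len(total_days %/% 7), n - 1))) * 7
    data.frame(subject = sprintf("S%d", s), day = days,
               value = 100 + rnorm(1, 0, b_sd) + slope * days + rnorm(n, 0, e_sd))
  })
  do.call(rbind, rows)
}
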
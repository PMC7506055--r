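# Shared fixtures and oracles for the test suite. Everything is generated in
# code; no data files.

# Greedy one-to-one matching of detected to ground-truth onsets.
match_events <- function(det_onsets, gt_onsets, tol = 5) {
  used <- logical(length(det_onsets))
  hits <- 0L
  for (o in gt_onsets) {
    d <- abs(det_onsets - o)
    d[used] <- Inf
    if (length(d) && min(d) <= tol) {
      used[which.min(d)] <- TRUE
      hits <- hits + 1L
    }
  }
  hits
}

# Detector recall/precision on one simulated trial, restricted to task
# saccades (amplitude >= min_amp); detections may match ground truth of any
# amplitude for the precision count.
detection_scores <- function(recording, ground_truth, min_amp = 2,
                             tol = 5) {
  det <- detect_saccades(recording)
  out <- c(recall = NA_real_, precision = NA_real_,
           n_gt = 0, n_det = 0)
  rec <- prec <- c()
  for (eye in c("left", "right")) {
    gt_all <- ground_truth$onset_index[ground_truth$eye == eye]
    gt_big <- ground_truth$onset_index[ground_truth$eye == eye &
                                         ground_truth$amplitude >= min_amp]
    d_all <- det$onset_index[det$eye == eye]
    d_big <- det$onset_index[det$eye == eye & det$amplitude >= min_amp]
    if (length(gt_big)) {
      rec <- c(rec, match_events(d_all, gt_big, tol) / length(gt_big))
    }
    if (length(d_big)) {
      prec <- c(prec, match_events(gt_all, d_big, tol) / length(d_big))
    }
  }
  c(recall = mean(rec), precision = mean(prec))
}

# One subject's named 80-entry STP vector under a (jittered) profile.
subject_stp <- function(profile, seed, jitter = TRUE) {
  set.seed(seed)
  prof <- if (jitter) gazescreen:::jitter_profile(profile, 0.1) else profile
  sub <- simulate_subject(prof, seed = seed)
  v <- extract_stp_vector(sub$recordings, sub$stimuli)
  stats::setNames(v$value, paste(v$feature_id, v$axis, v$condition, v$eye,
                                 sep = "."))
}

# Closed-form Welch t-test oracle (independent of stats::t.test).
welch_oracle <- function(a, b, direction = "a_greater") {
  na <- length(a); nb <- length(b)
  va <- var(a) / na; vb <- var(b) / nb
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (na - 1) + vb^2 / (nb - 1))
  p <- if (direction == "a_greater") pt(t, df, lower.tail = FALSE) else pt(t, df)
  list(t = t, df = df, p = p)
}

# Pentagon of well-separated identical Gaussian clusters.
planted_clusters <- function(seed, k = 5, per = 20, sep = 50, sd = 1) {
  set.seed(seed)
  ang <- 2 * pi * (seq_len(k) - 1) / k
  centers <- cbind(sep * cos(ang), sep * sin(ang))
  pts <- do.call(rbind, lapply(seq_len(k), function(j) {
    sweep(matrix(rnorm(2 * per, sd = sd), per, 2), 2, centers[j, ], "+")
  }))
  list(points = pts, labels = rep(seq_len(k), each = per))
}

# Amplitude-filtered directional profiles (both eyes) from the full
# protocol: one simulate + detect pass per subject.
subject_direction_profiles <- function(profile, seed, min_amp = 2) {
  sub <- simulate_subject(profile, seed = seed)
  s <- do.call(rbind, lapply(sub$recordings, detect_saccades))
  s <- s[s$amplitude >= min_amp & s$clean, , drop = FALSE]
  list(left = bin_directions(s[s$eye == "left", , drop = FALSE]),
       right = bin_directions(s[s$eye == "right", , drop = FALSE]))
}

# Right-nasal-hemifield saccade count for one eye's profile (bins within
# 60 degrees of rightward).
nasal_hemifield_count <- function(profile) {
  sum(profile$count[profile$bin_center_deg %in% c(300, 330, 0, 30, 60)])
}
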
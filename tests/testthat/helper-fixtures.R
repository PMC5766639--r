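# Shared fixture builders and independent oracles. Everything is built in
# code at test time; no binary fixtures.

# Noiseless IVIM series on the default 10-b scheme.
ivim_series_fixture <- function(f, D, D_star, S0 = 1,
                                scheme = default_bvalue_scheme()) {
  dwi_series(scheme, ivim_signal(ivim_params(f, D, D_star),
                                 scheme$b_values, S0 = S0))
}

# Independent brute-force hot-spot oracle: enumerate every candidate disc
# center by explicit loops, recomputing the disc membership from scratch.
hotspot_oracle <- function(values, elig, radius_mm, voxel_size, mode) {
  d <- dim(values)
  best <- NULL
  for (z in seq_len(d[3])) for (y in seq_len(d[2])) for (x in seq_len(d[1])) {
    members <- NULL
    ok <- TRUE
    for (yy in seq_len(d[2])) for (xx in seq_len(d[1])) {
      dist2 <- ((xx - x) * voxel_size[1])^2 + ((yy - y) * voxel_size[2])^2
      if (dist2 <= radius_mm^2 + 1e-9)
        members <- rbind(members, c(xx, yy))
    }
    # disc must be fully inside the eligible mask (and grid, by loop bounds);
    # voxels beyond the grid make the disc not fit:
    rx <- floor(radius_mm / voxel_size[1])
    ry <- floor(radius_mm / voxel_size[2])
    if (x - rx < 1 || x + rx > d[1] || y - ry < 1 || y + ry > d[2]) next
    for (k in seq_len(nrow(members)))
      if (!elig[members[k, 1], members[k, 2], z]) { ok <- FALSE; break }
    if (!ok) next
    m <- mean(values[cbind(members, z)])
    better <- if (is.null(best)) TRUE
      else if (mode == "max") m > best$mean else m < best$mean
    if (better) best <- list(center = c(x, y, z), mean = m)
  }
  best
}

# Independent Youden-threshold oracle: enumerate all cuts by hand.
# Mirrors the package convention: mid-gap candidate cuts, "> c" for the
# greater direction, "<= c" for less.
youden_oracle <- function(values, labels, positive = "high",
                          direction = c("greater", "less")) {
  direction <- match.arg(direction)
  pos <- labels == positive
  u <- sort(unique(values))
  cand <- c(-Inf, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, Inf)
  best <- NULL
  for (cc in cand) {
    pred <- if (direction == "greater") values > cc else values <= cc
    sens <- sum(pred & pos) / sum(pos)
    spec <- sum(!pred & !pos) / sum(!pos)
    j <- sens + spec - 1
    if (is.null(best) || j > best$youden + 1e-12 ||
        (abs(j - best$youden) <= 1e-12 && spec > best$spec + 1e-12))
      best <- list(threshold = cc, sens = sens, spec = spec, youden = j)
  }
  best
}
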
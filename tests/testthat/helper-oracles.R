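# Independent oracles used by the test suite. These deliberately avoid the
# package's own code paths: brute-force enumeration for assignment, a plain
# cumulative-sum random walk for persistence, and a Riemann sum for von
# Mises window masses.

# All one-to-one partial matchings between rows and cols of the distance
# matrix d, minimising sum of matched distances + gate per unmatched point;
# pairs with d > gate are forbidden. Returns matched pairs as a 2-col matrix.
oracle_assignment <- function(d, gate) {
  na <- nrow(d); nb <- ncol(d)
  best <- list(cost = Inf, pairs = matrix(integer(0), 0, 2))
  recurse <- function(i, used_b, pairs, cost) {
    if (i > na) {
      total <- cost + gate * (na - nrow(pairs)) + gate * (nb - nrow(pairs))
      if (total < best$cost - 1e-12) {
        best <<- list(cost = total, pairs = pairs)
      }
      return(invisible())
    }
    # leave i unmatched
    recurse(i + 1, used_b, pairs, cost)
    for (j in seq_len(nb)) {
      if (!used_b[j] && d[i, j] <= gate) {
        recurse(i + 1, `[<-`(used_b, j, TRUE),
                rbind(pairs, c(i, j)), cost + d[i, j])
      }
    }
  }
  recurse(1L, rep(FALSE, nb), matrix(integer(0), 0, 2), 0)
  best$pairs
}

# Frame-by-frame tracker built on oracle_assignment; same track semantics as
# link_tracks (new track on unmatched, no gap closing).
oracle_link <- function(detections, gate) {
  frames <- sort(unique(detections$frame))
  by_frame <- split(detections, factor(detections$frame, levels = frames))
  ids <- seq_len(nrow(by_frame[[1]]))
  next_id <- length(ids) + 1L
  out <- cbind(by_frame[[1]], track_id = ids)
  for (k in seq_along(frames)[-1]) {
    cur <- by_frame[[k - 1]]; nxt <- by_frame[[k]]
    d <- sqrt(outer(cur$x_um, nxt$x_um, "-")^2 +
              outer(cur$y_um, nxt$y_um, "-")^2)
    pairs <- oracle_assignment(d, gate)
    new_ids <- integer(nrow(nxt))
    for (b in seq_len(nrow(nxt))) {
      hit <- pairs[pairs[, 2] == b, 1]
      if (length(hit) == 1) {
        new_ids[b] <- ids[hit]
      } else {
        new_ids[b] <- next_id
        next_id <- next_id + 1L
      }
    }
    out <- rbind(out, cbind(nxt, track_id = new_ids))
    ids <- new_ids
  }
  out
}

# canonical form of a track table for equality comparison: list of position
# matrices keyed by (first frame, first position)
canonical_tracks <- function(tr) {
  sp <- split(tr[c("frame", "x_um", "y_um")], tr$track_id)
  sp <- lapply(sp, function(x) unname(as.matrix(x[order(x$frame), ])))
  keys <- vapply(sp, function(m) paste(round(m[1, ], 6), collapse = "_"),
                 character(1))
  unname(sp[order(keys)])
}

# isotropic random walk persistence oracle: plain cumsum walk
oracle_isotropic_persistence <- function(n_tracks, n_steps, speed_mean,
                                         speed_sd, seed) {
  set.seed(seed)
  vapply(seq_len(n_tracks), function(i) {
    th <- runif(n_steps, -pi, pi)
    sp <- rnorm(n_steps, speed_mean, speed_sd)
    while (any(sp < 0)) sp[sp < 0] <- rnorm(sum(sp < 0), speed_mean, speed_sd)
    dx <- sp * cos(th); dy <- sp * sin(th)
    net <- sqrt(sum(dx)^2 + sum(dy)^2)
    net / sum(sp)
  }, numeric(1))
}

# Riemann-sum von Mises mass on a closed window (independent of the
# package's integrate()-based quadrature)
riemann_vm_mass <- function(kappa, mu_deg = 90, window = c(60, 120),
                            n = 20000) {
  h <- diff(window) / n
  th <- window[1] + (seq_len(n) - 0.5) * h  # midpoint rule, error O(1/n^2)
  dens <- exp(kappa * cos((th - mu_deg) * pi / 180)) /
    (2 * pi * besselI(kappa, 0)) * (pi / 180)
  sum(dens) * h
}

# disc + k radial spur masks for filopodia / sprout fixtures
disc_mask <- function(side, centre, radius) {
  ix <- matrix(seq_len(side), side, side)
  iy <- t(ix)
  (ix - centre[1])^2 + (iy - centre[2])^2 <= radius^2
}

# add a 1-px-wide radial spur along angle_deg from radius r0 to r1
add_spur <- function(mask, centre, angle_deg, r0, r1, width_px = 1) {
  ix <- matrix(seq_len(nrow(mask)), nrow(mask), ncol(mask))
  iy <- t(ix)
  a <- angle_deg * pi / 180
  dx <- ix - centre[1]; dy <- iy - centre[2]
  along <- dx * cos(a) + dy * sin(a)
  perp <- abs(-dx * sin(a) + dy * cos(a))
  mask | (along >= r0 & along <= r1 & perp <= width_px / 2)
}

expect_within_3se <- function(observed, expected, n) {
  se <- sqrt(expected * (1 - expected) / n)
  expect_lt(abs(observed - expected), 3 * se + 1e-12)
}

# fresh temporary directory per call (unique under tempdir())
withr_like_tempdir <- function(prefix) {
  d <- file.path(tempdir(), paste0(prefix, "-", as.integer(Sys.time()),
                                   "-", sample.int(1e6, 1)))
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}
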
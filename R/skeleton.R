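# Zhang-Suen morphological thinning of a logical matrix. Returns a
# 1-pixel-wide 8-connected skeleton. Vectorised over the image per
# sub-iteration; masks here are small (tip-cell crops), so the iteration
# count is modest.
skeletonize <- function(mask) {
  stopifnot(is.matrix(mask))
  img <- mask != 0
  pad <- matrix(FALSE, nrow(img) + 2, ncol(img) + 2)
  pad[2:(nrow(img) + 1), 2:(ncol(img) + 1)] <- img
  nx <- nrow(pad); ny <- ncol(pad)
  shift <- function(m, dx, dy) {
    out <- matrix(FALSE, nx, ny)
    sx <- seq(max(1, 1 + dx), min(nx, nx + dx))
    sy <- seq(max(1, 1 + dy), min(ny, ny + dy))
    out[sx, sy] <- m[sx - dx, sy - dy]
    out
  }
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      # neighbours P2..P9 clockwise from north; rows = x, cols = y, so
      # 'north' is y+1
      p2 <- shift(pad, 0, 1);  p3 <- shift(pad, 1, 1)
      p4 <- shift(pad, 1, 0);  p5 <- shift(pad, 1, -1)
      p6 <- shift(pad, 0, -1); p7 <- shift(pad, -1, -1)
      p8 <- shift(pad, -1, 0); p9 <- shift(pad, -1, 1)
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      seq9 <- list(p2, p3, p4, p5, p6, p7, p8, p9, p2)
      a <- matrix(0L, nx, ny)
      for (k in 1:8) a <- a + (!seq9[[k]] & seq9[[k + 1]])
      if (step == 1) {
        cond <- pad & b >= 2 & b <= 6 & a == 1 &
          !(p2 & p4 & p6) & !(p4 & p6 & p8)
      } else {
        cond <- pad & b >= 2 & b <= 6 & a == 1 &
          !(p2 & p4 & p8) & !(p2 & p6 & p8)
      }
      if (any(cond)) {
        pad[cond] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  pad[2:(nrow(img) + 1), 2:(ncol(img) + 1)]
}

# 8-neighbour count for each skeleton pixel
skeleton_neighbour_count <- function(skel) {
  nx <- nrow(skel); ny <- ncol(skel)
  cnt <- matrix(0L, nx, ny)
  for (dx in -1:1) for (dy in -1:1) {
    if (dx == 0 && dy == 0) next
    sx <- seq(max(1, 1 + dx), min(nx, nx + dx))
    sy <- seq(max(1, 1 + dy), min(ny, ny + dy))
    cnt[sx, sy] <- cnt[sx, sy] + skel[sx - dx, sy - dy]
  }
  cnt
}

# Walk the skeleton from an endpoint until a junction (>= 3 neighbours) or a
# pixel whose local width reaches width_stop. Returns the branch pixel index
# matrix (endpoint first).
walk_branch <- function(skel, width2, endpoint, width_stop) {
  path <- matrix(endpoint, ncol = 2)
  cur <- endpoint
  nbr_cnt <- skeleton_neighbour_count(skel)
  nb <- expand.grid(dx = -1:1, dy = -1:1)
  nb <- nb[!(nb$dx == 0 & nb$dy == 0), ]
  repeat {
    cand <- cbind(cur[1] + nb$dx, cur[2] + nb$dy)
    ok <- cand[, 1] >= 1 & cand[, 1] <= nrow(skel) &
      cand[, 2] >= 1 & cand[, 2] <= ncol(skel)
    cand <- cand[ok, , drop = FALSE]
    cand <- cand[skel[cand], , drop = FALSE]
    if (nrow(cand) > 0) {
      on_path <- vapply(seq_len(nrow(cand)), function(k) {
        any(path[, 1] == cand[k, 1] & path[, 2] == cand[k, 2])
      }, logical(1))
      cand <- cand[!on_path, , drop = FALSE]
    }
    if (nrow(cand) == 0) break          # isolated spur
    if (nrow(cand) > 1) break           # junction reached
    nxt <- as.integer(cand[1, ])
    if (nbr_cnt[nxt[1], nxt[2]] >= 3) break   # entering a junction pixel
    if (width2[nxt[1], nxt[2]] >= width_stop) break  # entering the body
    cur <- nxt
    path <- rbind(path, cur)
  }
  path
}
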
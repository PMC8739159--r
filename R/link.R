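#' Link per-frame detections into tracks
#'
#' Frame-to-frame one-to-one assignment minimising total linkage distance
#' under a hard distance gate, solved as an optimal bipartite assignment on
#' the standard padded cost matrix (links cost their Euclidean distance when
#' within the gate and are forbidden beyond it; unmatched detections pay the
#' gate as a birth/death cost, start new tracks, or terminate old ones). No
#' gap closing: a track that misses a frame ends.
#'
#' @param detections Data frame with columns `frame`, `x_um`, `y_um`
#'   (additional columns are ignored). Frames may be any increasing integer
#'   labels; missing frames break all tracks.
#' @param max_disp_um Gate: maximum frame-to-frame displacement (> 0).
#' @return Tibble with `track_id`, `frame`, `x_um`, `y_um`.
#' @export
link_tracks <- function(detections, max_disp_um) {
  stopifnot(is.data.frame(detections))
  if (!is.finite(max_disp_um) || max_disp_um <= 0) {
    abort("max_disp_um must be a positive, finite gate.")
  }
  need <- c("frame", "x_um", "y_um")
  stopifnot(all(need %in% names(detections)))
  if (nrow(detections) == 0) {
    return(tibble::tibble(track_id = integer(), frame = integer(),
                          x_um = numeric(), y_um = numeric()))
  }
  frames <- sort(unique(detections$frame))
  by_frame <- split(detections[need], factor(detections$frame, levels = frames))
  n1 <- nrow(by_frame[[1]])
  # active track id per detection row of the current frame
  out <- list()
  next_id <- 1L
  cur <- by_frame[[1]]
  cur_ids <- if (n1 > 0) seq_len(n1) else integer(0)
  next_id <- n1 + 1L
  out[[1]] <- dplyr::mutate(cur, track_id = cur_ids)
  for (k in seq_along(frames)[-1]) {
    nxt <- by_frame[[k]]
    contiguous <- frames[k] == frames[k - 1] + 1
    na <- nrow(cur); nb <- nrow(nxt)
    match_b <- rep(NA_integer_, nb)
    if (contiguous && na > 0 && nb > 0) {
      d <- sqrt(outer(cur$x_um, nxt$x_um, "-")^2 +
                outer(cur$y_um, nxt$y_um, "-")^2)
      assn <- gated_assignment(d, max_disp_um)
      match_b[assn$j] <- assn$i
    }
    ids <- integer(nb)
    for (b in seq_len(nb)) {
      if (!is.na(match_b[b])) {
        ids[b] <- cur_ids[match_b[b]]
      } else {
        ids[b] <- next_id
        next_id <- next_id + 1L
      }
    }
    out[[k]] <- dplyr::mutate(nxt, track_id = ids)
    cur <- nxt
    cur_ids <- ids
  }
  res <- dplyr::bind_rows(out)
  tibble::as_tibble(res[c("track_id", "frame", "x_um", "y_um")]) |>
    dplyr::arrange(.data$track_id, .data$frame)
}

# Optimal gated one-to-one assignment between two point sets given their
# distance matrix d (rows = frame t, cols = frame t+1). Returns the linked
# pairs (i, j). Padded square LSAP: top-left d (gated), birth/death diagonal
# blocks at cost = gate, lower-right zero block.
gated_assignment <- function(d, gate) {
  na <- nrow(d); nb <- ncol(d)
  BIG <- max(gate, max(d[is.finite(d)], 0)) * 1e6 + 1
  size <- na + nb
  cost <- matrix(BIG, size, size)
  dd <- d
  dd[dd > gate] <- BIG
  cost[seq_len(na), seq_len(nb)] <- dd
  for (i in seq_len(na)) cost[i, nb + i] <- gate       # death of i
  for (j in seq_len(nb)) cost[na + j, j] <- gate       # birth of j
  cost[(na + 1):size, (nb + 1):size] <- 0              # auxiliary block
  sol <- as.integer(clue::solve_LSAP(cost))
  i <- seq_len(na)
  j <- sol[seq_len(na)]
  ok <- j <= nb & d[cbind(i, pmin(j, nb))] <= gate
  list(i = i[ok], j = j[ok])
}
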
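#' Link localized features into trajectories
#'
#' Frame-to-frame linking in the Crocker-Grier spirit: between consecutive
#' frames, candidate pairs closer than `max_displacement` are assigned
#' one-to-one so as to minimize the total squared displacement, with an
#' unlinked track or feature costing `max_displacement^2`. The candidate
#' graph is split into connected subnetworks that are solved exactly by
#' enumeration (ties broken in favour of lower particle id); a pathological
#' subnetwork with more than `subnet_cap` possible assignments raises an
#' error advising a smaller `max_displacement`. Unmatched features start
#' new trajectories. With `memory > 0` a track that misses up to `memory`
#' consecutive frames may be resumed from its last known position.
#'
#' @param features data.frame with columns `frame` (0-based), `x`, `y`
#'   (px), and optionally `mass`, `size`, `ecc`; rows in any order.
#' @param max_displacement Search radius in px (> 0).
#' @param memory Frames a particle may go missing (default 0).
#' @param fps Frames per second of the source video.
#' @param pixel_size um per px; positions are converted to um.
#' @param subnet_cap Enumeration cap per subnetwork.
#' @return A [traj_ensemble()] (positions in um) with extra columns
#'   `x_px`, `y_px` and any feature columns carried through.
#' @export
link_features <- function(features, max_displacement = 5, memory = 0L,
                          fps = 60, pixel_size = 0.1, subnet_cap = 1e5) {
  stopifnot(max_displacement > 0, memory >= 0L)
  if (nrow(features) == 0L) stop("no features to link")
  features <- features[order(features$frame), , drop = FALSE]
  frames <- min(features$frame):max(features$frame)
  maxd2 <- max_displacement^2

  tracks_x <- numeric(0); tracks_y <- numeric(0)
  tracks_last <- integer(0); tracks_id <- integer(0)
  next_id <- 1L
  out_rows <- vector("list", length(frames))
  by_frame <- split(seq_len(nrow(features)), features$frame)

  for (fi in seq_along(frames)) {
    f <- frames[fi]
    rows <- by_frame[[as.character(f)]]
    if (is.null(rows)) rows <- integer(0)
    cx <- features$x[rows]; cy <- features$y[rows]
    m <- length(rows)
    assigned <- rep(NA_integer_, m)           # track index per candidate

    live <- which(tracks_last >= f - 1L - memory)
    if (length(live) && m) {
      d2 <- outer(tracks_x[live], cx, "-")^2 +
            outer(tracks_y[live], cy, "-")^2
      allowed <- d2 <= maxd2
      comp <- bipartite_components(allowed)
      for (cmp in comp) {
        sol <- solve_subnet(d2[cmp$tracks, cmp$cands, drop = FALSE],
                            allowed[cmp$tracks, cmp$cands, drop = FALSE],
                            maxd2, subnet_cap,
                            tracks_id[live][cmp$tracks])
        hit <- !is.na(sol)
        assigned[cmp$cands[hit]] <- live[cmp$tracks[sol[hit]]]
      }
    }
    # update matched tracks, start new ones for unmatched candidates
    for (j in seq_len(m)) {
      if (is.na(assigned[j])) {
        tracks_x <- c(tracks_x, cx[j]); tracks_y <- c(tracks_y, cy[j])
        tracks_last <- c(tracks_last, f)
        tracks_id <- c(tracks_id, next_id)
        assigned[j] <- length(tracks_id)
        next_id <- next_id + 1L
      } else {
        ti <- assigned[j]
        tracks_x[ti] <- cx[j]; tracks_y[ti] <- cy[j]
        tracks_last[ti] <- f
      }
    }
    if (m)
      out_rows[[fi]] <- data.frame(particle = tracks_id[assigned],
                                   frame = f, row = rows)
  }
  res <- do.call(rbind, out_rows)
  extra <- intersect(c("mass", "size", "ecc"), names(features))
  df <- data.frame(particle = res$particle, frame = res$frame,
                   x = features$x[res$row] * pixel_size,
                   y = features$y[res$row] * pixel_size,
                   x_px = features$x[res$row],
                   y_px = features$y[res$row])
  for (col in extra) df[[col]] <- features[[col]][res$row]
  traj_ensemble(df, fps = fps, pixel_size = pixel_size)
}

# Connected components of the bipartite track-candidate graph given the
# logical adjacency matrix. Components with no edges are dropped.
bipartite_components <- function(allowed) {
  nt <- nrow(allowed); nc <- ncol(allowed)
  seen_t <- rep(FALSE, nt); seen_c <- rep(FALSE, nc)
  comps <- list()
  for (t0 in seq_len(nt)) {
    if (seen_t[t0] || !any(allowed[t0, ])) next
    qt <- t0; ts <- integer(0); cs <- integer(0)
    seen_t[t0] <- TRUE
    qc <- integer(0)
    while (length(qt) || length(qc)) {
      if (length(qt)) {
        t <- qt[1]; qt <- qt[-1]; ts <- c(ts, t)
        nb <- which(allowed[t, ] & !seen_c)
        seen_c[nb] <- TRUE; qc <- c(qc, nb)
      } else {
        c <- qc[1]; qc <- qc[-1]; cs <- c(cs, c)
        nb <- which(allowed[, c] & !seen_t)
        seen_t[nb] <- TRUE; qt <- c(qt, nb)
      }
    }
    comps[[length(comps) + 1L]] <- list(tracks = sort(ts), cands = sort(cs))
  }
  comps
}

# Exact minimum-cost assignment within one subnetwork by depth-first
# enumeration over tracks (ascending id order, so cost ties resolve in
# favour of the lower particle id). Returns, per candidate, the index of
# the matched track within the subnetwork, or NA.
solve_subnet <- function(d2, allowed, maxd2, subnet_cap, ids) {
  nt <- nrow(d2); nc <- ncol(d2)
  n_leaves <- prod(rowSums(allowed) + 1)
  if (n_leaves > subnet_cap)
    stop("linking subnetwork with ", nt, " tracks x ", nc, " candidates is ",
         "too large to solve exactly; lower max_displacement")
  ord <- order(ids)
  best_cost <- Inf
  best_match <- rep(NA_integer_, nc)
  used <- rep(FALSE, nc)
  match <- rep(NA_integer_, nc)

  recurse <- function(k, cost) {
    if (cost >= best_cost) return()
    if (k > nt) {
      # unmatched candidates start new tracks at cost maxd2 each
      total <- cost + maxd2 * sum(is.na(match))
      if (total < best_cost) {
        best_cost <<- total
        best_match <<- match
      }
      return()
    }
    t <- ord[k]
    for (j in which(allowed[t, ] & !used)) {
      used[j] <<- TRUE; match[j] <<- t
      recurse(k + 1L, cost + d2[t, j])
      used[j] <<- FALSE; match[j] <<- NA_integer_
    }
    recurse(k + 1L, cost + maxd2)          # leave track t unlinked
  }
  recurse(1L, 0)
  best_match
}
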
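# Double-sided T-maze geometry, linearization, and along-track distances.
#
# The maze is modeled as a tree with two junction nodes: the forced point F
# (where the two forced arms meet the stem) and the choice point C (where the
# stem meets the two choice arms). Reward sites sit at the distal ends of the
# choice arms. Every on-track point is addressed by (arm, u) where u is the
# along-arm distance in cm from the arm's junction node (the stem is measured
# from F), and by a global linearized coordinate obtained by concatenating the
# arms in a fixed order. All distances are geodesic along the track.

ARM_ORDER <- c("forced_left", "forced_right", "stem", "choice_left", "choice_right")

#' Build a double-sided T-maze
#'
#' Constructs the maze geometry used by the whole pipeline: two forced arms and
#' two choice arms of length `arm_length`, joined by a central stem of length
#' `stem_length`, with reward sites at the ends of the choice arms. Coordinates
#' are in cm with the forced point at the origin and the stem along the x-axis.
#'
#' @param arm_length length of each forced and choice arm, cm
#' @param stem_length length of the central stem, cm
#' @return an object of class `maze_geometry` with components `arms`
#'   (per-arm endpoints, lengths and linearization offsets), `reward_sites`,
#'   and `total_length`
#' @export
#' @examples
#' mz <- build_maze(100, 100)
#' mz$total_length  # 4*100 + 100
build_maze <- function(arm_length = 100, stem_length = 100) {
  if (arm_length <= 0 || stem_length <= 0)
    stop("arm_length and stem_length must be positive")
  A <- arm_length; S <- stem_length
  arms <- data.frame(
    label = ARM_ORDER,
    x0 = c(0, 0, 0, S, S),
    y0 = c(0, 0, 0, 0, 0),
    x1 = c(0, 0, S, S, S),
    y1 = c(A, -A, 0, A, -A),
    length = c(A, A, S, A, A),
    junction = c("F", "F", "F", "C", "C"),
    stringsAsFactors = FALSE
  )
  arms$offset <- cumsum(c(0, arms$length[-nrow(arms)]))
  reward_sites <- data.frame(
    site = c("left", "right"),
    arm = c("choice_left", "choice_right"),
    x = c(S, S), y = c(A, -A),
    stringsAsFactors = FALSE
  )
  structure(list(
    arm_length = A, stem_length = S, arms = arms,
    reward_sites = reward_sites, total_length = 4 * A + S
  ), class = "maze_geometry")
}

#' @export
print.maze_geometry <- function(x, ...) {
  cat("Double-sided T maze: arm", x$arm_length, "cm, stem", x$stem_length,
      "cm, linearized extent", x$total_length, "cm\n")
  invisible(x)
}

# distances from an on-track point (arm, u) to the two junction nodes
.node_dists <- function(arm, u, maze) {
  S <- maze$stem_length
  dF <- ifelse(arm == "stem", u, ifelse(arm %in% c("forced_left", "forced_right"), u, u + S))
  dC <- ifelse(arm == "stem", S - u, ifelse(arm %in% c("choice_left", "choice_right"), u, u + S))
  list(dF = dF, dC = dC)
}

#' Project 2-D points onto the track
#'
#' Maps each (x, y) cm point to its nearest maze segment, returning the arm
#' label, the along-arm coordinate, the global linearized coordinate, and an
#' off-track flag for points farther than `tol` from every segment. At
#' junctions, ties are broken by the fixed arm priority order (forced arms,
#' stem, choice arms).
#'
#' @param x,y point coordinates in cm
#' @param maze a `maze_geometry`
#' @param tol off-track tolerance, cm
#' @return data.frame with columns `arm`, `u`, `lin`, `dist`, `off_track`
#' @export
linearize <- function(x, y, maze, tol = 10) {
  n <- length(x)
  best_d <- rep(Inf, n); best_arm <- rep(NA_character_, n)
  best_u <- rep(NA_real_, n)
  for (i in seq_len(nrow(maze$arms))) {
    a <- maze$arms[i, ]
    vx <- a$x1 - a$x0; vy <- a$y1 - a$y0
    tt <- pmin(pmax(((x - a$x0) * vx + (y - a$y0) * vy) / a$length^2, 0), 1)
    dx <- x - (a$x0 + tt * vx); dy <- y - (a$y0 + tt * vy)
    d <- sqrt(dx^2 + dy^2)
    upd <- d < best_d - 1e-12  # strict: earlier arms win ties
    best_d[upd] <- d[upd]; best_arm[upd] <- a$label; best_u[upd] <- tt[upd] * a$length
  }
  off <- best_d > tol
  # keep arm coordinates inside the half-open [0, length) range so the global
  # linearized coordinate stays unambiguous at arm ends
  lens <- maze$arms$length[match(best_arm, maze$arms$label)]
  best_u <- pmin(best_u, lens - 1e-9)
  lin <- maze$arms$offset[match(best_arm, maze$arms$label)] + best_u
  data.frame(arm = best_arm, u = best_u, lin = lin, dist = best_d,
             off_track = off, stringsAsFactors = FALSE)
}

# convert global linearized coordinates back to (arm, u)
.lin_to_arm <- function(lin, maze) {
  idx <- findInterval(lin, c(maze$arms$offset, maze$total_length + 1e-9),
                      rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), nrow(maze$arms))
  data.frame(arm = maze$arms$label[idx], u = lin - maze$arms$offset[idx],
             stringsAsFactors = FALSE)
}

#' Along-track distance between points
#'
#' Geodesic distance along the maze between two sets of points given as global
#' linearized coordinates. Vectorized over pairs (recycled).
#'
#' @param lin1,lin2 global linearized coordinates, cm
#' @param maze a `maze_geometry`
#' @return distances in cm
#' @export
path_distance <- function(lin1, lin2, maze) {
  p <- .lin_to_arm(lin1, maze); q <- .lin_to_arm(lin2, maze)
  n <- max(nrow(p), nrow(q))
  p <- p[rep_len(seq_len(nrow(p)), n), , drop = FALSE]
  q <- q[rep_len(seq_len(nrow(q)), n), , drop = FALSE]
  np <- .node_dists(p$arm, p$u, maze); nq <- .node_dists(q$arm, q$u, maze)
  d <- pmin(np$dF + nq$dF, np$dC + nq$dC)
  same <- p$arm == q$arm
  d[same] <- abs(p$u[same] - q$u[same])
  d
}

#' Along-track distance to a reward site
#'
#' @param lin global linearized coordinate(s), cm
#' @param maze a `maze_geometry`
#' @param context `"left"`, `"right"`, or `"nearest"` (minimum over the two
#'   reward sites)
#' @return distance in cm (0 at the reward site)
#' @export
distance_to_reward <- function(lin, maze, context = "nearest") {
  pa <- .lin_to_arm(lin, maze)
  nd <- .node_dists(pa$arm, pa$u, maze)
  A <- maze$arm_length; S <- maze$stem_length
  one <- function(arm_lab) {
    # reward sits at the distal end (u = A) of the given choice arm, whose
    # node distances are dF = A + S, dC = A
    d <- pmin(nd$dF + A + S, nd$dC + A)
    same <- pa$arm == arm_lab
    d[same] <- A - pa$u[same]
    d
  }
  dl <- one("choice_left"); dr <- one("choice_right")
  switch(context, left = dl, right = dr, pmin(dl, dr))
}

#' Bin the linearized track
#'
#' Partitions each arm into half-open `[lo, hi)` bins of width `bin_size`
#' (the last bin of an arm may be shorter) and precomputes the structures the
#' mapping stages need: bin centers in global linearized coordinates, the
#' bin adjacency implied by the maze graph (consecutive bins within an arm,
#' plus junction-crossing links), and the matrix of pairwise geodesic
#' distances between bin centers used by the mask-normalized smoother.
#'
#' @param maze a `maze_geometry`
#' @param bin_size bin width, cm
#' @return a `track_grid` object with `bins` (data.frame: arm, lo, hi, center
#'   as global lin), `adj` (adjacency list), `D` (distance matrix), `bin_size`
#' @export
track_grid <- function(maze, bin_size) {
  if (bin_size <= 0) stop("bin_size must be positive")
  bins <- do.call(rbind, lapply(seq_len(nrow(maze$arms)), function(i) {
    a <- maze$arms[i, ]
    lo <- seq(0, a$length - 1e-9, by = bin_size)
    hi <- pmin(lo + bin_size, a$length)
    data.frame(arm = a$label, lo = lo, hi = hi,
               center = a$offset + (lo + hi) / 2,
               lin_lo = a$offset + lo, lin_hi = a$offset + hi,
               stringsAsFactors = FALSE)
  }))
  rownames(bins) <- NULL
  n <- nrow(bins)
  # adjacency: within-arm neighbours plus junction-crossing links
  adj <- vector("list", n)
  for (i in seq_len(n - 1)) {
    if (bins$arm[i] == bins$arm[i + 1]) {
      adj[[i]] <- c(adj[[i]], i + 1L); adj[[i + 1]] <- c(adj[[i + 1]], i)
    }
  }
  first_bin <- function(arm) which(bins$arm == arm & bins$lo == 0)
  last_bin <- function(arm) {
    w <- which(bins$arm == arm); w[which.max(bins$hi[w])]
  }
  link <- function(i, j) {
    adj[[i]] <<- unique(c(adj[[i]], j)); adj[[j]] <<- unique(c(adj[[j]], i))
  }
  # forced point F joins forced arms and stem start; choice point C joins
  # stem end and choice arms
  fF <- c(first_bin("forced_left"), first_bin("forced_right"), first_bin("stem"))
  for (i in fF) for (j in fF) if (i < j) link(i, j)
  fC <- c(last_bin("stem"), first_bin("choice_left"), first_bin("choice_right"))
  for (i in fC) for (j in fC) if (i < j) link(i, j)
  # pairwise geodesic distances between bin centers (vectorized via node dists)
  pa <- .lin_to_arm(bins$center, maze)
  nd <- .node_dists(pa$arm, pa$u, maze)
  D <- pmin(outer(nd$dF, nd$dF, "+"), outer(nd$dC, nd$dC, "+"))
  same <- outer(pa$arm, pa$arm, "==")
  du <- abs(outer(pa$u, pa$u, "-"))
  D[same] <- du[same]
  structure(list(bins = bins, adj = adj, D = D, bin_size = bin_size,
                 maze = maze), class = "track_grid")
}

# assign linearized coordinates to grid bins (NA if outside any bin)
.grid_bin <- function(grid, lin) {
  pa <- .lin_to_arm(lin, grid$maze)
  out <- rep(NA_integer_, length(lin))
  for (a in unique(pa$arm)) {
    sel <- which(pa$arm == a)
    b <- grid$bins[grid$bins$arm == a, ]
    rows <- which(grid$bins$arm == a)
    k <- findInterval(pa$u[sel], c(b$lo, b$hi[nrow(b)]), rightmost.closed = TRUE)
    k[k < 1 | k > nrow(b)] <- NA_integer_
    out[sel] <- rows[k]
  }
  out
}
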
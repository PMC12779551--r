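# Topology-preserving thinning, spur pruning and geometric skeleton length.
# Implemented here because no installed package provides 2-D morphological
# skeletonization; all operations are vectorized over the full pixel grid.

# Shift a matrix by (di, dj), zero-filling the exposed border.
shift_mat <- function(m, di, dj) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0L, nr, nc)
  ri <- max(1, 1 + di):min(nr, nr + di)
  rj <- max(1, 1 + dj):min(nc, nc + dj)
  out[ri, rj] <- m[ri - di, rj - dj]
  out
}

# 8-neighbourhood of each pixel, in Zhang-Suen order P2..P9
# (P2 = north, then clockwise). Rows increase downward.
neighbor_stack <- function(m) {
  list(p2 = shift_mat(m, 1, 0),   # value of northern neighbour
       p3 = shift_mat(m, 1, -1),
       p4 = shift_mat(m, 0, -1),
       p5 = shift_mat(m, -1, -1),
       p6 = shift_mat(m, -1, 0),
       p7 = shift_mat(m, -1, 1),
       p8 = shift_mat(m, 0, 1),
       p9 = shift_mat(m, 1, 1))
}

#' Skeletonize a binary mask by Zhang-Suen thinning
#'
#' Iterative two-subcycle thinning that reduces a binary mask to a
#' one-pixel-wide, 8-connected skeleton while preserving topology.
#'
#' @param mask Logical or 0/1 matrix.
#' @return Logical matrix of the same shape.
#' @export
skeletonize <- function(mask) {
  m <- matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      nb <- neighbor_stack(m)
      b <- nb$p2 + nb$p3 + nb$p4 + nb$p5 + nb$p6 + nb$p7 + nb$p8 + nb$p9
      seqs <- list(nb$p2, nb$p3, nb$p4, nb$p5, nb$p6, nb$p7, nb$p8, nb$p9,
                   nb$p2)
      a <- matrix(0L, nrow(m), ncol(m))
      for (k in 1:8) a <- a + (seqs[[k]] == 0L & seqs[[k + 1L]] == 1L)
      cond <- m == 1L & b >= 2L & b <= 6L & a == 1L
      if (step == 1) {
        cond <- cond & (nb$p2 * nb$p4 * nb$p6 == 0L) &
          (nb$p4 * nb$p6 * nb$p8 == 0L)
      } else {
        cond <- cond & (nb$p2 * nb$p4 * nb$p8 == 0L) &
          (nb$p2 * nb$p6 * nb$p8 == 0L)
      }
      if (any(cond)) { m[cond] <- 0L; changed <- TRUE }
    }
    if (!changed) break
  }
  m == 1L
}

# Number of 8-connected skeleton neighbours of each pixel.
neighbor_count <- function(m) {
  mi <- matrix(as.integer(m), nrow(m), ncol(m))
  nb <- neighbor_stack(mi)
  nb$p2 + nb$p3 + nb$p4 + nb$p5 + nb$p6 + nb$p7 + nb$p8 + nb$p9
}

#' Remove short spur branches from a skeleton
#'
#' Walks inward from each skeleton endpoint; a branch that reaches a
#' junction (pixel with three or more neighbours) within
#' `prune_um / pixel_size_um` of geometric length is removed. Open curves
#' that terminate at another endpoint are never shortened, so isolated
#' filaments keep their full length.
#'
#' @param skel Logical skeleton matrix.
#' @param prune_um Maximum spur length to remove, in micrometres.
#' @param pixel_size_um Micrometres per pixel.
#' @return Pruned logical skeleton matrix.
#' @export
prune_spurs <- function(skel, prune_um = 5, pixel_size_um = 1) {
  if (prune_um <= 0) return(skel)
  max_len <- prune_um / pixel_size_um
  nr <- nrow(skel)
  offs <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
                c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
  step_len <- c(1, 1, 1, 1, sqrt(2), sqrt(2), sqrt(2), sqrt(2))
  repeat {
    nc_mat <- neighbor_count(skel)
    ends <- which(skel & nc_mat == 1L, arr.ind = TRUE)
    if (nrow(ends) == 0L) break
    removed_any <- FALSE
    for (e in seq_len(nrow(ends))) {
      path <- list(ends[e, ])
      len <- 0
      cur <- ends[e, ]
      prev <- c(NA_integer_, NA_integer_)
      repeat {
        hit <- NULL
        for (k in 1:8) {
          ni <- cur[1] + offs[k, 1]; nj <- cur[2] + offs[k, 2]
          if (ni < 1 || nj < 1 || ni > nr || nj > ncol(skel)) next
          if (!skel[ni, nj]) next
          if (!is.na(prev[1]) && ni == prev[1] && nj == prev[2]) next
          hit <- c(ni, nj, step_len[k]); break
        }
        if (is.null(hit)) { len <- Inf; break }  # isolated open curve end
        len <- len + hit[3]
        if (len > max_len) { len <- Inf; break }
        nxt <- c(hit[1], hit[2])
        deg <- nc_mat[nxt[1], nxt[2]]
        if (deg >= 3L) break                      # reached a junction: spur
        if (deg == 1L) { len <- Inf; break }      # other endpoint: not a spur
        prev <- cur; cur <- nxt
        path[[length(path) + 1L]] <- cur
      }
      if (is.finite(len)) {
        for (p in path) skel[p[1], p[2]] <- FALSE
        removed_any <- TRUE
      }
    }
    if (!removed_any) break
  }
  skel
}

#' Geometric length of a skeleton
#'
#' Sum over adjacent skeleton pixel pairs of the step length: 1 for
#' 4-neighbour (horizontal/vertical) pairs and sqrt(2) for diagonal pairs,
#' scaled by the pixel size. Each pair is counted once, and a diagonal
#' pair whose two pixels also share a common 4-neighbour inside the
#' skeleton is skipped: in the staircase corners that thinning can leave,
#' the path already runs through the shared neighbour, and counting the
#' diagonal shortcut as well would double-count the step. The sqrt(2)
#' diagonal weight matters: a pixel-count "length" understates a diagonal
#' segment by up to 41 percent.
#'
#' @param skel Logical skeleton matrix.
#' @param pixel_size_um Micrometres per pixel.
#' @return Length in micrometres.
#' @export
skeleton_length_um <- function(skel, pixel_size_um = 1) {
  m <- matrix(as.integer(skel), nrow(skel), ncol(skel))
  if (sum(m) == 0L) return(0)
  n_h <- sum(m * shift_mat(m, 0, 1))
  n_v <- sum(m * shift_mat(m, 1, 0))
  # diagonal pair (i,j)-(i+1,j+1): common 4-neighbours (i+1,j), (i,j+1)
  d1 <- m * shift_mat(m, 1, 1)
  d1_ok <- d1 * (1 - pmin(shift_mat(m, 1, 0) + shift_mat(m, 0, 1), 1))
  # anti-diagonal pair (i,j)-(i+1,j-1): common 4-neighbours (i+1,j), (i,j-1)
  d2 <- m * shift_mat(m, 1, -1)
  d2_ok <- d2 * (1 - pmin(shift_mat(m, 1, 0) + shift_mat(m, 0, -1), 1))
  (n_h + n_v + sqrt(2) * (sum(d1_ok) + sum(d2_ok))) * pixel_size_um
}
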
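# Discretization and grey-level matrix builders. All matrices are computed on
# a VOI cropped to its bounding box, with voxels outside the VOI set to NA so
# neighbourhood operations never cross the VOI boundary.

# The 13 unique 3D directions of the 26-neighbourhood (one per +/- pair),
# ordered lexicographically with the leading nonzero component positive.
unique_directions <- function() {
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  keep <- offs[, 3] > 0 | (offs[, 3] == 0 & offs[, 2] > 0) |
    (offs[, 3] == 0 & offs[, 2] == 0 & offs[, 1] > 0)
  offs[keep, , drop = FALSE]
}

#' Fixed-bin-number discretization
#'
#' Maps raw intensities to integer grey levels `1..n_bins` with bin width
#' `(max - min) / n_bins` computed from the VOI's own range; the maximum
#' maps to `n_bins`. A constant VOI maps to a single level.
#'
#' @param values Numeric vector of VOI intensities.
#' @param n_bins Number of grey levels (default 64).
#' @return Integer vector of grey levels.
#' @export
discretize_fbn <- function(values, n_bins = 64) {
  rng <- range(values)
  if (diff(rng) == 0) {
    return(rep(1L, length(values)))
  }
  w <- diff(rng) / n_bins
  pmin(as.integer(floor((values - rng[1]) / w)) + 1L, as.integer(n_bins))
}

# Aligned voxel pairs for one offset: matrix with columns (value at p,
# value at p + off), both inside the VOI.
offset_pairs <- function(arr, off) {
  d <- dim(arr)
  if (any(d <= abs(off))) return(NULL)
  idx <- lapply(1:3, function(ax) {
    o <- off[ax]
    if (o >= 0) list(a = seq_len(d[ax] - o), b = seq_len(d[ax] - o) + o)
    else list(a = seq(1 - o, d[ax]), b = seq_len(d[ax] + o))
  })
  v1 <- arr[idx[[1]]$a, idx[[2]]$a, idx[[3]]$a]
  v2 <- arr[idx[[1]]$b, idx[[2]]$b, idx[[3]]$b]
  keep <- !is.na(v1) & !is.na(v2)
  if (!any(keep)) return(NULL)
  cbind(v1[keep], v2[keep])
}

# Grey-level co-occurrence matrix: symmetric counts summed over the 13
# unique directions at single-voxel offset (equivalent, after the final
# normalisation, to averaging the per-direction matrices).
glcm_matrix <- function(arr, n_levels) {
  P <- matrix(0, n_levels, n_levels)
  for (i in seq_len(nrow(unique_directions()))) {
    pr <- offset_pairs(arr, unique_directions()[i, ])
    if (is.null(pr)) next
    counts <- tabulate((pr[, 1] - 1L) * n_levels + pr[, 2], nbins = n_levels^2)
    M <- matrix(counts, n_levels, n_levels, byrow = TRUE)
    P <- P + M + t(M)
  }
  P
}

# Grey-level run-length matrix summed over the 13 directions. Runs are found
# by sorting voxels along each direction's lattice lines: a line is the set
# of voxels sharing p - t*d, with t the coordinate along the first nonzero
# component of d.
glrlm_matrix <- function(arr, n_levels) {
  d <- dim(arr)
  coords <- arrayInd(which(!is.na(arr)), d)
  g <- arr[!is.na(arr)]
  max_run <- max(d)
  P <- matrix(0, n_levels, max_run)
  dirs <- unique_directions()
  for (k in seq_len(nrow(dirs))) {
    dk <- dirs[k, ]
    ax <- which(dk != 0)[1]
    t <- coords[, ax] * dk[ax]
    lid <- coords - outer(t, dk)
    key <- (lid[, 1] + d[1]) + (2 * d[1] + 1) * ((lid[, 2] + d[2]) +
             (2 * d[2] + 1) * (lid[, 3] + d[3]))
    ord <- order(key, t)
    ks <- key[ord]; ts <- t[ord]; gs <- g[ord]
    brk <- c(TRUE, ks[-1] != ks[-length(ks)] | ts[-1] != ts[-length(ts)] + 1L |
               gs[-1] != gs[-length(gs)])
    run_id <- cumsum(brk)
    run_len <- tabulate(run_id)
    run_g <- gs[brk]
    P <- P + matrix(tabulate((run_g - 1L) * max_run + run_len,
                             nbins = n_levels * max_run),
                    n_levels, max_run, byrow = TRUE)
  }
  P
}

# Grey-level size-zone matrix: 26-connected zones of equal grey level.
glszm_matrix <- function(arr, n_levels) {
  d <- dim(arr)
  lin <- which(!is.na(arr))
  n <- length(lin)
  pos <- integer(length(arr))
  pos[lin] <- seq_len(n)
  dirs <- unique_directions()
  edges <- list()
  coords <- arrayInd(lin, d)
  for (k in seq_len(nrow(dirs))) {
    dk <- dirs[k, ]
    nb <- coords + rep(dk, each = n)
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    if (!any(ok)) next
    nb_lin <- nb[ok, 1] + d[1] * (nb[ok, 2] - 1) + d[1] * d[2] * (nb[ok, 3] - 1)
    src <- lin[ok]
    both <- pos[nb_lin] > 0 & arr[src] == arr[nb_lin]
    if (!any(both)) next
    edges[[length(edges) + 1]] <- cbind(pos[src][both], pos[nb_lin][both])
  }
  memb <- if (length(edges)) {
    gr <- igraph::graph_from_edgelist(do.call(rbind, edges), directed = FALSE)
    gr <- igraph::add_vertices(gr, max(0, n - igraph::vcount(gr)))
    igraph::components(gr)$membership
  } else {
    seq_len(n)
  }
  zone_size <- tabulate(memb)
  # grey level of each zone (constant within a zone by construction)
  zone_g <- vapply(split(arr[lin], memb), function(v) v[1], numeric(1))
  max_size <- max(zone_size)
  matrix(tabulate((as.integer(zone_g) - 1L) * max_size + zone_size,
                  nbins = n_levels * max_size),
         n_levels, max_size, byrow = TRUE)
}

# Grey-level dependence matrix (alpha = 0): dependence of a voxel is
# 1 + the number of 26-neighbours inside the VOI with the same grey level.
gldm_matrix <- function(arr, n_levels) {
  d <- dim(arr)
  dep <- array(0L, d)
  dirs <- unique_directions()
  for (k in seq_len(nrow(dirs))) {
    for (sgn in c(1L, -1L)) {
      off <- dirs[k, ] * sgn
      if (any(d <= abs(off))) next
      idx <- lapply(1:3, function(ax) {
        o <- off[ax]
        if (o >= 0) list(a = seq_len(d[ax] - o), b = seq_len(d[ax] - o) + o)
        else list(a = seq(1 - o, d[ax]), b = seq_len(d[ax] + o))
      })
      v1 <- arr[idx[[1]]$a, idx[[2]]$a, idx[[3]]$a]
      v2 <- arr[idx[[1]]$b, idx[[2]]$b, idx[[3]]$b]
      eq <- !is.na(v1) & !is.na(v2) & v1 == v2
      sub <- dep[idx[[1]]$a, idx[[2]]$a, idx[[3]]$a]
      sub[eq] <- sub[eq] + 1L
      dep[idx[[1]]$a, idx[[2]]$a, idx[[3]]$a] <- sub
    }
  }
  inside <- !is.na(arr)
  j <- dep[inside] + 1L
  g <- arr[inside]
  max_dep <- max(j)
  matrix(tabulate((g - 1L) * max_dep + j, nbins = n_levels * max_dep),
         n_levels, max_dep, byrow = TRUE)
}

# Neighbouring grey-tone difference matrix ingredients: for each grey level
# i, the occurrence probability p_i and the summed absolute difference s_i
# between voxels of level i and the mean of their in-VOI 26-neighbours.
# Voxels with no in-VOI neighbour are excluded.
ngtdm_table <- function(arr, n_levels) {
  d <- dim(arr)
  nb_sum <- array(0, d)
  nb_cnt <- array(0L, d)
  dirs <- unique_directions()
  vals <- arr
  vals[is.na(vals)] <- 0
  present <- !is.na(arr)
  for (k in seq_len(nrow(dirs))) {
    for (sgn in c(1L, -1L)) {
      off <- dirs[k, ] * sgn
      if (any(d <= abs(off))) next
      idx <- lapply(1:3, function(ax) {
        o <- off[ax]
        if (o >= 0) list(a = seq_len(d[ax] - o), b = seq_len(d[ax] - o) + o)
        else list(a = seq(1 - o, d[ax]), b = seq_len(d[ax] + o))
      })
      sa <- nb_sum[idx[[1]]$a, idx[[2]]$a, idx[[3]]$a] +
        vals[idx[[1]]$b, idx[[2]]$b, idx[[3]]$b]
      ca <- nb_cnt[idx[[1]]$a, idx[[2]]$a, idx[[3]]$a] +
        present[idx[[1]]$b, idx[[2]]$b, idx[[3]]$b]
      nb_sum[idx[[1]]$a, idx[[2]]$a, idx[[3]]$a] <- sa
      nb_cnt[idx[[1]]$a, idx[[2]]$a, idx[[3]]$a] <- ca
    }
  }
  use <- present & nb_cnt > 0
  g <- arr[use]
  abar <- nb_sum[use] / nb_cnt[use]
  nvp <- length(g)
  n_i <- tabulate(g, nbins = n_levels)
  s_i <- numeric(n_levels)
  agg <- tapply(abs(g - abar), g, sum)
  s_i[as.integer(names(agg))] <- agg
  list(p = n_i / max(nvp, 1), s = s_i, n = n_i, nvp = nvp,
       levels = seq_len(n_levels))
}
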
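#' Ring topology over N synapses
#'
#' Synapses are placed at fixed indices on a ring; the distance between two
#' synapses is the minimal path length along the ring (with wraparound), so
#' `distance <= floor(N/2)`.  This is the 1D neighborhood used for the
#' exponential depression-leakage kernel.
#'
#' @param N number of synapses, `>= 3`.
#' @return an object of class `c("ring_topology", "synapse_topology")`.
#' @examples
#' topo <- ring_topology(10)
#' topo_distance(topo, 1, 10)  # wraparound: 1
#' @export
ring_topology <- function(N) {
  if (length(N) != 1L || !is.finite(N) || N < 3)
    stop("'N' must be an integer >= 3")
  structure(list(N = as.integer(N)),
            class = c("ring_topology", "synapse_topology"))
}

#' Number of synapses in a topology
#' @param topology a `synapse_topology`.
#' @return integer count.
#' @export
n_synapses <- function(topology) UseMethod("n_synapses")

#' @export
n_synapses.ring_topology <- function(topology) topology$N

#' @export
n_synapses.spatial_layout <- function(topology) nrow(topology$coords)

#' Pairwise distance between synapses
#'
#' Ring topologies measure minimal path length on the ring (in synapse
#' steps); spatial layouts measure Euclidean distance in micrometers.
#' `i` and `j` are recycled against each other.
#'
#' @param topology a `synapse_topology`.
#' @param i,j 1-based synapse indices.
#' @return numeric vector of distances.
#' @export
topo_distance <- function(topology, i, j) UseMethod("topo_distance")

#' @export
topo_distance.ring_topology <- function(topology, i, j) {
  N <- topology$N
  a <- abs(as.integer(i) - as.integer(j)) %% N
  pmin(a, N - a)
}

#' @export
topo_distance.spatial_layout <- function(topology, i, j) {
  d <- topology$coords[i, , drop = FALSE] - topology$coords[j, , drop = FALSE]
  sqrt(rowSums(d * d))
}

#' @export
print.ring_topology <- function(x, ...) {
  cat(sprintf("ring_topology: %d synapses\n", x$N))
  invisible(x)
}

#' @export
print.spatial_layout <- function(x, ...) {
  cat(sprintf("spatial_layout (%s): %d spines on %d compartments\n",
              x$provenance, nrow(x$coords),
              length(unique(x$compartment))))
  invisible(x)
}

new_spatial_layout <- function(coords, compartment, provenance) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  colnames(coords) <- c("x", "y", "z")
  structure(list(coords = coords,
                 compartment = as.integer(compartment),
                 provenance = provenance,
                 cache = new.env(parent = emptyenv())),
            class = c("spatial_layout", "synapse_topology"))
}

unit_vec <- function(v) v / sqrt(sum(v * v))

# any vector perpendicular to v (v nonzero)
perp_vec <- function(v) {
  a <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  cross3(v, a)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Generate a surrogate spiny-dendrite morphology
#'
#' Grows a random branched tree of straight dendritic compartments and studs
#' each compartment with equally spaced spines along its axis, emulating a
#' Purkinje-cell spiny dendrite carrying one parallel-fibre synapse per
#' spine.  Defaults give 1474 compartments x 10 spines = 14,740 synapses
#' with 0.3 um spine spacing (total dendritic length about 4.4 mm), so that
#' the inter-spine distance statistics at the micrometer scale relevant for
#' Gaussian leakage kernels (sigma of 0.25-0.75 um) are realistic.  The
#' exact reconstructed morphology behind the biophysical model is not
#' reproduced; only the distance statistics matter here.
#'
#' Spine `s` of a compartment of length `L` attaches at axial position
#' `(s - 1/2) L / spines_per_compartment`, so the intra-compartment
#' attachment spacing is exactly `L / spines_per_compartment`.  Each spine
#' head — where the synapse sits — is displaced from its attachment point
#' by `spine_neck_length` perpendicular to the compartment axis in a
#' random direction, as on a real spiny dendrite; Purkinje spines measure
#' about 1-1.5 um from shaft to head, hence the 1 um default.  Set
#' `spine_neck_length = 0` to place synapses directly on the axis.
#'
#' @param n_compartments number of dendritic compartments.
#' @param spines_per_compartment spines (synapses) per compartment.
#' @param compartment_length compartment length in micrometers.
#' @param branch_probability probability that a compartment spawns a new
#'   branch at its distal end.
#' @param spine_neck_length perpendicular offset of each spine head from
#'   the dendritic axis, in micrometers.
#' @param branch_separation self-avoidance distance in micrometers
#'   (default 6, of the order of the spacing between spiny branchlets in
#'   the arbor, i.e. arbor area over total dendritic length):
#'   candidate growth directions whose endpoint comes closer than this to
#'   any non-adjacent compartment are resampled (dendritic branchlets do
#'   not intersect; without this, a random tree tangles and unrelated
#'   branches contribute spurious sub-micrometer spine neighbors).
#' @param seed integer seed for the random tree.
#' @return a `spatial_layout` with `provenance = "generated"`.
#' @examples
#' lay <- build_synthetic_morphology(20, 10, 3.0, seed = 1)
#' n_synapses(lay)
#' @export
build_synthetic_morphology <- function(n_compartments = 1474,
                                       spines_per_compartment = 10,
                                       compartment_length = 3.0,
                                       branch_probability = 0.1,
                                       spine_neck_length = 1.0,
                                       branch_separation = 6,
                                       seed = NULL) {
  if (n_compartments < 1 || spines_per_compartment < 1 ||
      compartment_length <= 0 || spine_neck_length < 0)
    stop("invalid morphology parameters")
  if (branch_separation < 0) stop("'branch_separation' must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  s <- as.integer(spines_per_compartment)
  L <- compartment_length
  # active growth tips: position, direction, and the indices of the last
  # few endpoints of the tip's own path in 'ends' (exempt from the
  # self-avoidance check; a freshly branched tip inherits its parent's,
  # so siblings may stay close near the branch point before diverging)
  tip_pos <- list(c(0, 0, 0))
  tip_dir <- list(unit_vec(stats::rnorm(3)))
  tip_ex <- list(1L)
  coords <- matrix(0, nrow = n_compartments * s, ncol = 3)
  compartment <- integer(n_compartments * s)
  ends <- matrix(0, nrow = n_compartments + 1L, ncol = 3)  # compartment endpoints
  n_ends <- 1L
  off <- (seq_len(s) - 0.5) / s * L
  sep2 <- branch_separation^2
  for (k in seq_len(n_compartments)) {
    t <- sample.int(length(tip_pos), 1L)
    p0 <- tip_pos[[t]]
    # self-avoidance: resample the heading until the new endpoint keeps its
    # distance from all earlier compartment endpoints (the attachment point
    # itself lies one compartment length away, beyond the separation);
    # fall back to the least-crowded candidate
    best_dir <- NULL
    best_clear <- -Inf
    eseq <- setdiff(seq_len(n_ends), tip_ex[[t]])
    epts <- ends[eseq, , drop = FALSE]
    for (try in 1:50) {
      dir <- unit_vec(tip_dir[[t]] + stats::rnorm(3, sd = 0.25))
      clear <- if (nrow(epts)) {
        p1 <- p0 + L * dir
        pm <- p0 + 0.5 * L * dir
        min(pmin(rowSums(sweep(epts, 2, p1)^2),
                 rowSums(sweep(epts, 2, pm)^2)))
      } else Inf
      if (clear > best_clear) { best_clear <- clear; best_dir <- dir }
      if (clear >= sep2) break
    }
    dir <- best_dir
    rows <- ((k - 1L) * s + 1L):(k * s)
    coords[rows, ] <- rep(p0, each = s) + off %*% t(dir)
    if (spine_neck_length > 0) {
      # spine necks point in random directions perpendicular to the axis
      u <- unit_vec(perp_vec(dir))
      v <- cross3(dir, u)
      phi <- stats::runif(s, 0, 2 * pi)
      coords[rows, ] <- coords[rows, ] +
        spine_neck_length * (cos(phi) %*% t(u) + sin(phi) %*% t(v))
    }
    compartment[rows] <- k
    p1 <- p0 + L * dir
    n_ends <- n_ends + 1L
    ends[n_ends, ] <- p1
    tip_pos[[t]] <- p1
    tip_dir[[t]] <- dir
    tip_ex[[t]] <- c(n_ends, utils::head(tip_ex[[t]], 3L))
    if (stats::runif(1) < branch_probability) {
      tip_pos[[length(tip_pos) + 1L]] <- p1
      tip_dir[[length(tip_dir) + 1L]] <- unit_vec(stats::rnorm(3))
      tip_ex[[length(tip_ex) + 1L]] <- tip_ex[[t]]
    }
  }
  new_spatial_layout(coords, compartment, "generated")
}

#' Import a spine layout from SWC or CSV
#'
#' SWC files (the standard neuronal-morphology interchange format) are read
#' one sample point per spine, taking the x, y, z columns in micrometers;
#' compartment indices are not represented in SWC and are assigned
#' sequentially.  CSV files must carry an `x,y,z` header and may add a
#' `compartment_id` column.
#'
#' @param path file path.
#' @param format `"swc"`, `"csv"`, or `"auto"` (by file extension).
#' @return a `spatial_layout` with `provenance = "imported"`.
#' @export
read_layout <- function(path, format = c("auto", "swc", "csv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.swc$", path, ignore.case = TRUE)) "swc" else "csv"
  if (format == "swc") {
    lines <- readLines(path)
    keep <- which(!grepl("^\\s*(#|$)", lines))
    if (!length(keep)) stop("SWC file contains no sample points: ", path)
    rows <- vector("list", length(keep))
    for (ii in seq_along(keep)) {
      ln <- keep[ii]
      fields <- suppressWarnings(as.numeric(strsplit(trimws(lines[ln]),
                                                     "\\s+")[[1]]))
      if (length(fields) != 7L || anyNA(fields))
        stop(sprintf("malformed SWC record at line %d of %s", ln, path))
      rows[[ii]] <- fields
    }
    m <- do.call(rbind, rows)
    new_spatial_layout(m[, 3:5, drop = FALSE], seq_len(nrow(m)), "imported")
  } else {
    df <- utils::read.csv(path)
    if (!all(c("x", "y", "z") %in% names(df)))
      stop("CSV layout must have x,y,z columns: ", path)
    comp <- if ("compartment_id" %in% names(df)) df$compartment_id
            else seq_len(nrow(df))
    new_spatial_layout(as.matrix(df[, c("x", "y", "z")]), comp, "imported")
  }
}

#' Export a spine layout to SWC or CSV
#'
#' SWC export chains the spines of each compartment (parent = previous spine
#' of the same compartment, first spine a root); coordinates are written
#' with 6 decimals, so an export/import round trip preserves them to 1e-6.
#'
#' @param layout a `spatial_layout`.
#' @param path file path.
#' @param format `"swc"`, `"csv"`, or `"auto"` (by file extension).
#' @return `path`, invisibly.
#' @export
write_layout <- function(layout, path, format = c("auto", "swc", "csv")) {
  stopifnot(inherits(layout, "spatial_layout"))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.swc$", path, ignore.case = TRUE)) "swc" else "csv"
  n <- nrow(layout$coords)
  if (format == "swc") {
    parent <- rep(-1L, n)
    if (n > 1) {
      same <- layout$compartment[-1] == layout$compartment[-n]
      parent[-1][same] <- which(same)   # previous row within the compartment
    }
    lines <- sprintf("%d 6 %.6f %.6f %.6f 0.100000 %d",
                     seq_len(n), layout$coords[, 1], layout$coords[, 2],
                     layout$coords[, 3], parent)
    writeLines(c("# id type x y z radius parent", lines), path)
  } else {
    df <- data.frame(x = round(layout$coords[, 1], 6),
                     y = round(layout$coords[, 2], 6),
                     z = round(layout$coords[, 3], 6),
                     compartment_id = layout$compartment)
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

# Fixed-radius neighbor lists on a spatial layout via a grid cell-list:
# points are bucketed into cubic cells of edge 'cutoff' and each point is
# compared only against the 27 surrounding cells.  Results (indices and
# distances, self excluded) are cached on the layout, keyed by cutoff.
spatial_neighbors <- function(layout, cutoff) {
  key <- sprintf("nb_%.9g", cutoff)
  hit <- get0(key, envir = layout$cache, inherits = FALSE)
  if (!is.null(hit)) return(hit)
  xyz <- layout$coords
  n <- nrow(xyz)
  ci <- floor(sweep(xyz, 2, apply(xyz, 2, min)) / cutoff)
  span <- apply(ci, 2, max) + 1
  code <- ci[, 1] + span[1] * (ci[, 2] + span[2] * ci[, 3])
  buckets <- split(seq_len(n), code)
  bkeys <- as.numeric(names(buckets))
  idx <- vector("list", n)
  dst <- vector("list", n)
  sq <- rowSums(xyz * xyz)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  cut2 <- cutoff^2
  for (b in seq_along(buckets)) {
    pts <- buckets[[b]]
    c0 <- ci[pts[1], ]
    neigh_codes <- (c0[1] + offs[, 1]) +
      span[1] * ((c0[2] + offs[, 2]) + span[2] * (c0[3] + offs[, 3]))
    cand <- unlist(buckets[match(neigh_codes, bkeys, nomatch = 0L)],
                   use.names = FALSE)
    # squared distances of every point in this bucket to every candidate
    d2 <- outer(sq[pts], sq[cand], "+") -
      2 * (xyz[pts, , drop = FALSE] %*% t(xyz[cand, , drop = FALSE]))
    for (ii in seq_along(pts)) {
      i <- pts[ii]
      sel <- which(d2[ii, ] <= cut2 & cand != i)
      o <- cand[sel]
      d <- sqrt(pmax(d2[ii, sel], 0))
      idx[[i]] <- o
      dst[[i]] <- d
    }
  }
  res <- list(idx = idx, dist = dst)
  assign(key, res, envir = layout$cache)
  res
}
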
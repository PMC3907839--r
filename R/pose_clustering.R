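# Docked-pose selection: RMSD matrix -> nearest-neighbor clustering ->
# central structures -> active-site filter -> up to three MD starting poses
# per (ligand, template). Coordinates are in nm throughout.

#' Construct a set of docked ligand poses
#'
#' Container for docked conformations of one ligand in one protein template:
#' an ordered list of atomic coordinate matrices sharing atom count and
#' ordering, in nm.
#'
#' @param coords List of n_atoms x 3 numeric matrices (nm), one per pose.
#' @param ligand_id,template_id Identifiers carried along to outputs.
#' @param pose_ids Optional character labels, default `"pose1"`, ...
#' @return An object of class `pose_set`.
#' @seealso [read_pose_pdb()], [select_md_poses()]
#' @export
pose_set <- function(coords, ligand_id = "ligand", template_id = "template",
                     pose_ids = NULL) {
  stopifnot(is.list(coords), length(coords) >= 1)
  coords <- lapply(coords, function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    m
  })
  n_atoms <- nrow(coords[[1]])
  for (k in seq_along(coords)) {
    if (nrow(coords[[k]]) != n_atoms || ncol(coords[[k]]) != 3)
      stop(sprintf("pose %d: expected %d x 3 coordinates, got %d x %d",
                   k, n_atoms, nrow(coords[[k]]), ncol(coords[[k]])),
           call. = FALSE)
    if (any(!is.finite(coords[[k]])))
      stop(sprintf("pose %d has non-finite coordinates", k), call. = FALSE)
  }
  if (is.null(pose_ids)) pose_ids <- paste0("pose", seq_along(coords))
  stopifnot(length(pose_ids) == length(coords))
  structure(list(ligand_id = ligand_id, template_id = template_id,
                 coords = coords, pose_ids = as.character(pose_ids),
                 n_atoms = n_atoms),
            class = "pose_set")
}

#' @export
print.pose_set <- function(x, ...) {
  cat(sprintf("<pose_set> %s in %s: %d pose(s), %d atoms each\n",
              x$ligand_id, x$template_id, length(x$coords), x$n_atoms))
  invisible(x)
}

#' @export
length.pose_set <- function(x) length(x$coords)

#' Pairwise RMSD matrix over a pose set
#'
#' Heavy-atom root-mean-square deviation between every pair of poses,
#' without rotational/translational superposition: poses docked into one
#' rigid template share a coordinate frame, and differences in binding
#' position are meaningful signal that fitting would erase. Optionally a
#' Kabsch superposition can be applied first for other uses.
#'
#' @param poses A [pose_set()] with at least 2 poses.
#' @param superpose If `TRUE`, least-squares superpose each pair before the
#'   RMSD (via [bio3d::fit.xyz()]); default `FALSE`.
#' @return Symmetric matrix (nm) with zero diagonal, of class
#'   `pose_distance_matrix`.
#' @export
pose_rmsd_matrix <- function(poses, superpose = FALSE) {
  stopifnot(inherits(poses, "pose_set"))
  n <- length(poses)
  if (n < 2) stop("need at least 2 poses", call. = FALSE)
  flat <- t(vapply(poses$coords, function(m) as.numeric(t(m)),
                   numeric(3 * poses$n_atoms)))
  if (superpose) {
    fitted <- bio3d::fit.xyz(fixed = flat[1, ], mobile = flat)
    m <- matrix(0, n, n)
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      fj <- bio3d::fit.xyz(fixed = flat[i, ], mobile = flat[j, , drop = FALSE])
      m[i, j] <- m[j, i] <-
        sqrt(sum((flat[i, ] - fj)^2) / poses$n_atoms)
    }
  } else {
    # RMSD_ij = ||x_i - x_j||_2 / sqrt(n_atoms): a scaled Euclidean distance
    m <- as.matrix(stats::dist(flat)) / sqrt(poses$n_atoms)
  }
  dimnames(m) <- list(poses$pose_ids, poses$pose_ids)
  class(m) <- c("pose_distance_matrix", class(m))
  m
}

check_distance_matrix <- function(matrix) {
  if (!is.matrix(matrix) || nrow(matrix) != ncol(matrix) || nrow(matrix) == 0)
    stop("distance matrix must be a non-empty square matrix", call. = FALSE)
  invisible(matrix)
}

#' Nearest-neighbor clustering of poses
#'
#' Greedy neighbor-count clustering on a pose-pose RMSD matrix: repeatedly
#' take the unassigned pose with the most unassigned neighbors within
#' `cutoff` (ties broken by lowest pose index), form a cluster of it plus
#' those neighbors, remove them, and repeat until everything is assigned or
#' `max_clusters` clusters have been emitted (leftover poses are reported as
#' unclustered). By construction cluster populations are non-increasing.
#'
#' @param matrix Symmetric pose-pose distance matrix (nm), e.g. from
#'   [pose_rmsd_matrix()].
#' @param cutoff Neighbor distance cutoff in nm (> 0). Default 0.2 nm.
#' @param max_clusters Maximum number of clusters to emit (default 5).
#' @return An object of class `pose_clusters`: list with `clusters` (each a
#'   list with integer `members` and `central`, the member minimizing the
#'   mean RMSD to the other members), `unclustered` (integer vector),
#'   `cutoff`.
#' @export
nearest_neighbor_cluster <- function(matrix, cutoff = 0.2, max_clusters = 5) {
  check_distance_matrix(matrix)
  stopifnot(is.numeric(cutoff), cutoff > 0,
            max_clusters >= 1, max_clusters == round(max_clusters))
  n <- nrow(matrix)
  adj <- matrix <= cutoff
  diag(adj) <- FALSE
  active <- rep(TRUE, n)
  clusters <- list()
  while (any(active) && length(clusters) < max_clusters) {
    counts <- ifelse(active, rowSums(adj[, active, drop = FALSE]), -1)
    center <- unname(which.max(counts))  # ties -> lowest index
    members <- sort(unname(c(center, which(adj[center, ] & active))))
    clusters[[length(clusters) + 1]] <-
      list(members = members,
           central = central_structure(members, matrix))
    active[members] <- FALSE
  }
  structure(list(clusters = clusters, unclustered = which(active),
                 cutoff = cutoff),
            class = "pose_clusters")
}

#' @export
print.pose_clusters <- function(x, ...) {
  sizes <- vapply(x$clusters, function(cl) length(cl$members), integer(1))
  cat(sprintf("<pose_clusters> %d cluster(s) at cutoff %.3g nm; sizes: %s; %d unclustered\n",
              length(x$clusters), x$cutoff, paste(sizes, collapse = ", "),
              length(x$unclustered)))
  invisible(x)
}

#' Central structure of a cluster
#'
#' The cluster member with the smallest average RMSD to the other members;
#' a singleton is its own central structure; ties go to the lowest pose
#' index.
#'
#' @param members Integer vector of member pose indices.
#' @param matrix The pose-pose distance matrix.
#' @return The central member's pose index.
#' @export
central_structure <- function(members, matrix) {
  check_distance_matrix(matrix)
  members <- sort(as.integer(members))
  if (length(members) == 0) stop("empty cluster", call. = FALSE)
  if (length(members) == 1) return(members)
  sub <- matrix[members, members, drop = FALSE]
  mean_dist <- rowSums(sub) / (length(members) - 1)
  unname(members[which.min(mean_dist)])
}

#' Discard pose clusters outside the active site
#'
#' A cluster is retained when the geometric center of its central structure
#' lies within `site_radius` of `site_center` (both nm); otherwise it is
#' discarded and logged with its distance. Emulates the manual triage of
#' docking solutions that land outside the catalytic site.
#'
#' @param clusters A `pose_clusters` object.
#' @param poses The [pose_set()] the clusters refer to.
#' @param site_center Numeric length-3 active-site center (nm).
#' @param site_radius Positive radius (nm).
#' @return List with `retained` (a `pose_clusters` object) and `discarded`
#'   (data frame with `cluster`, `central`, `distance_nm`).
#' @export
active_site_filter <- function(clusters, poses, site_center, site_radius) {
  stopifnot(inherits(clusters, "pose_clusters"), inherits(poses, "pose_set"))
  if (is.null(site_center) || is.null(site_radius))
    stop("active-site filter requested without `site_center`/`site_radius`",
         call. = FALSE)
  stopifnot(is.numeric(site_center), length(site_center) == 3,
            is.numeric(site_radius), site_radius > 0)
  dist_to_site <- vapply(clusters$clusters, function(cl) {
    ctr <- colMeans(poses$coords[[cl$central]])
    sqrt(sum((ctr - site_center)^2))
  }, numeric(1))
  keep <- dist_to_site <= site_radius
  discarded <- data.frame(cluster = which(!keep),
                          central = vapply(clusters$clusters[!keep],
                                           `[[`, integer(1), "central"),
                          distance_nm = dist_to_site[!keep])
  retained <- structure(list(clusters = clusters$clusters[keep],
                             unclustered = clusters$unclustered,
                             cutoff = clusters$cutoff),
                        class = "pose_clusters")
  list(retained = retained, discarded = discarded)
}

#' Select MD starting poses from docked conformations
#'
#' Full pose-selection pipeline for one (ligand, template): cluster the
#' poses (at most `max_clusters` clusters), optionally discard clusters
#' outside the active site, and return the central structures of the up to
#' three most populated retained clusters, tagged `"I"`, `"II"`, `"III"` by
#' population rank. If nothing survives the filter an empty selection is
#' returned with a warning rather than an error.
#'
#' @param poses A [pose_set()].
#' @param cutoff,max_clusters Clustering parameters, see
#'   [nearest_neighbor_cluster()].
#' @param site_center,site_radius Optional active-site definition (nm); both
#'   must be given to enable the filter.
#' @param n_select Number of clusters to harvest (default 3).
#' @return List with `poses` (a [pose_set()] of the selected central
#'   structures with pose ids `"I"`/`"II"`/`"III"`, or `NULL` when empty)
#'   and `report` (data frame: `rank`, `pose_index`, `population`).
#' @export
select_md_poses <- function(poses, cutoff = 0.2, max_clusters = 5,
                            site_center = NULL, site_radius = NULL,
                            n_select = 3) {
  stopifnot(inherits(poses, "pose_set"))
  if (length(poses) == 1) {
    sel <- pose_set(poses$coords, poses$ligand_id, poses$template_id, "I")
    return(list(poses = sel,
                report = data.frame(rank = "I", pose_index = 1L,
                                    population = 1L)))
  }
  mat <- pose_rmsd_matrix(poses)
  cl <- nearest_neighbor_cluster(mat, cutoff, max_clusters)
  if (xor(is.null(site_center), is.null(site_radius)))
    stop("supply both `site_center` and `site_radius`, or neither",
         call. = FALSE)
  if (!is.null(site_center))
    cl <- active_site_filter(cl, poses, site_center, site_radius)$retained
  if (length(cl$clusters) == 0) {
    warning("no pose cluster retained inside the active site; ",
            "empty selection", call. = FALSE)
    return(list(poses = NULL,
                report = data.frame(rank = character(0),
                                    pose_index = integer(0),
                                    population = integer(0))))
  }
  take <- seq_len(min(n_select, length(cl$clusters)))
  centrals <- vapply(cl$clusters[take], `[[`, integer(1), "central")
  pops <- vapply(cl$clusters[take], function(x) length(x$members), integer(1))
  ranks <- c("I", "II", "III", as.character(seq_along(take)))[seq_along(take)]
  sel <- pose_set(poses$coords[centrals], poses$ligand_id, poses$template_id,
                  pose_ids = ranks)
  list(poses = sel,
       report = data.frame(rank = ranks, pose_index = centrals,
                           population = pops))
}
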
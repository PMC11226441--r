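#' Construct a neutral facial-landmark mesh
#'
#' A neutral mesh is the reference configuration from which all motion is
#' expressed as displacement fields. It carries `K` dimensionless 3D
#' landmark coordinates and a named region map partitioning the landmark
#' indices into `head_rigid`, `left_periocular`, `right_periocular`,
#' `perioral` and `other`. Two topologies are available:
#'
#' * `"toy"` — a procedural front-facing layout with regions assigned by
#'   index blocks; any `K >= 12` is allowed (default 64). Fast and
#'   sufficient for all motion analysis, which never uses anatomical
#'   semantics beyond the region grouping.
#' * `"facemesh468"` — the canonical 468-landmark face-mesh topology with
#'   region index sets read from a packaged JSON map (approximate
#'   periocular/perioral/quasi-rigid groupings; coordinates are a
#'   synthetic procedural stand-in, since landmark analysis here is
#'   topology- not geometry-dependent).
#'
#' Construction is deterministic: the same `topology_id` and `K` always
#' yield identical coordinates and regions.
#'
#' @param topology_id `"toy"` or `"facemesh468"`.
#' @param K Number of landmarks. Must be 468 for `"facemesh468"`,
#'   otherwise any integer `>= 12`.
#' @return An object of class `neutral_mesh`: a list with elements
#'   `coords` (K x 3 matrix), `region_map` (named list of integer index
#'   vectors), `topology_id` and `K`.
#' @examples
#' mesh <- make_neutral_mesh("toy", 32)
#' lengths(mesh$region_map)
#' @export
make_neutral_mesh <- function(topology_id = "toy", K = 64L) {
  if (!is.character(topology_id) || length(topology_id) != 1L) {
    stopf("`topology_id` must be a single string")
  }
  if (identical(topology_id, "toy")) {
    K <- check_count(K, "K", lower = 12L)
    region_map <- toy_region_map(K)
  } else if (identical(topology_id, "facemesh468")) {
    if (!missing(K) && K != 468L) stopf("topology 'facemesh468' requires K = 468")
    K <- 468L
    region_map <- read_region_map(
      system.file("extdata", "facemesh468_regions.json", package = "agencymix"),
      K = K
    )
  } else {
    stopf("unknown topology_id '%s' (available: 'toy', 'facemesh468')",
          topology_id, class = "agencymix_config_error")
  }
  mesh <- structure(
    list(coords = face_layout(K), region_map = region_map,
         topology_id = topology_id, K = K),
    class = "neutral_mesh"
  )
  validate_mesh(mesh)
}

# Deterministic quasi-uniform layout on a front-facing ellipsoid cap
# (golden-angle spiral). Dimensionless units, face spans roughly [-1, 1].
face_layout <- function(K) {
  i <- seq_len(K)
  golden <- pi * (3 - sqrt(5))
  r <- sqrt((i - 0.5) / K)
  phi <- golden * i
  cbind(
    x = 0.8 * r * cos(phi),
    y = 1.0 * r * sin(phi),
    z = 0.45 * sqrt(pmax(0, 1 - r^2))
  )
}

# Index-block region assignment used by the toy topology. Guarantees every
# region (including `other`) is non-empty for K >= 12.
toy_region_map <- function(K) {
  n_head <- max(3L, ceiling(0.30 * K))
  n_eye <- max(2L, ceiling(0.15 * K))
  n_mouth <- max(2L, ceiling(0.20 * K))
  stopifnot(n_head + 2L * n_eye + n_mouth < K)
  cuts <- cumsum(c(n_head, n_eye, n_eye, n_mouth))
  list(
    head_rigid = seq_len(cuts[1]),
    left_periocular = seq.int(cuts[1] + 1L, cuts[2]),
    right_periocular = seq.int(cuts[2] + 1L, cuts[3]),
    perioral = seq.int(cuts[3] + 1L, cuts[4]),
    other = seq.int(cuts[4] + 1L, K)
  )
}

# Read a packaged or user-supplied region-map JSON. The file stores index
# sets for the named regions (0- or 1-based per its `index_base` field);
# `other` is completed as the remaining indices.
read_region_map <- function(path, K) {
  if (!nzchar(path) || !file.exists(path)) {
    stopf("region-map file not found: '%s'", path, class = "agencymix_config_error")
  }
  spec <- jsonlite::read_json(path, simplifyVector = TRUE)
  base <- spec$index_base %||% 0L
  regions <- lapply(spec$regions, function(idx) as.integer(idx) + (1L - base))
  needed <- c("head_rigid", "left_periocular", "right_periocular", "perioral")
  missing_regions <- setdiff(needed, names(regions))
  if (length(missing_regions)) {
    stopf("region map '%s' lacks regions: %s", path,
          paste(missing_regions, collapse = ", "),
          class = "agencymix_config_error")
  }
  regions <- regions[needed]
  used <- sort(unlist(regions))
  if (any(used < 1L | used > K) || anyDuplicated(used)) {
    stopf("region map '%s' has out-of-range or duplicated indices", path,
          class = "agencymix_config_error")
  }
  regions$other <- setdiff(seq_len(K), used)
  regions
}

validate_mesh <- function(mesh) {
  stopifnot(inherits(mesh, "neutral_mesh"))
  if (!is.matrix(mesh$coords) || ncol(mesh$coords) != 3L ||
      !all(is.finite(mesh$coords))) {
    stopf("mesh coordinates must be a finite K x 3 matrix")
  }
  if (nrow(mesh$coords) < 12L) stopf("a mesh needs K >= 12 landmarks")
  rm <- mesh$region_map
  if (any(lengths(rm) == 0L)) stopf("every mesh region must be non-empty")
  idx <- unlist(rm, use.names = FALSE)
  if (anyDuplicated(idx)) stopf("mesh regions must be disjoint")
  if (any(idx < 1L | idx > nrow(mesh$coords))) stopf("region indices out of range")
  mesh
}

#' @export
print.neutral_mesh <- function(x, ...) {
  cat(sprintf("<neutral_mesh> topology '%s', K = %d landmarks\n",
              x$topology_id, x$K))
  cat("regions:",
      paste(sprintf("%s (%d)", names(x$region_map), lengths(x$region_map)),
            collapse = ", "), "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
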
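# Anthropometric table: segment mass fractions, COM locations and radii of
# gyration, loaded from a YAML config so users can substitute their own
# published table.

#' Load an anthropometric table
#'
#' Reads per-segment mass fractions, segment-length fractions of stature,
#' COM locations (fraction of segment length from the proximal end) and
#' principal radii of gyration (fraction of segment length) from a YAML
#' config. The bundled default is a de Leva-style adjusted-Zatsiorsky table
#' with the head folded into the torso and the hand into the forearm, so the
#' 12 modeled segments (pelvis, torso, left/right upper arm, forearm, thigh,
#' shank, foot) carry the entire body mass.
#'
#' @param path path to a YAML table; `NULL` loads the bundled default.
#' @return an object of class `anthropometric_table`: a named list of
#'   per-segment parameter lists.
#' @export
anthropometric_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "anthropometry.yaml", package = "momnet")
  cfg <- yaml::read_yaml(path)
  segs <- cfg$segments
  if (is.null(segs) || !length(segs)) stop("table has no 'segments' entry")
  for (nm in names(segs)) {
    s <- segs[[nm]]
    if (!is.numeric(s$mass_fraction) || s$mass_fraction <= 0 || s$mass_fraction >= 1)
      stop("mass_fraction for '", nm, "' must lie in (0, 1)")
    if (any(unlist(s$gyration) < 0) || any(unlist(s$gyration) >= 1))
      stop("radii of gyration for '", nm, "' must lie in [0, 1)")
    if (s$com_fraction <= 0 || s$com_fraction >= 1)
      stop("com_fraction for '", nm, "' must lie in (0, 1)")
  }
  # paired segments (arms/legs) count twice toward the whole-body mass
  paired <- c("upper_arm", "forearm", "thigh", "shank", "foot")
  total <- sum(vapply(names(segs), function(nm) {
    segs[[nm]]$mass_fraction * if (nm %in% paired) 2 else 1
  }, numeric(1)))
  if (total > 1 + 1e-9)
    stop("segment mass fractions sum to ", round(total, 4), " > 1")
  structure(segs, class = "anthropometric_table", modeled_fraction = total)
}

#' Segment mass, COM offset and local inertia tensor
#'
#' Derives a segment's inertial parameters from the anthropometric table:
#' mass as a fraction of total body mass, COM offset along the segment long
#' axis, and a diagonal local inertia tensor with
#' \eqn{I_{jj} = m (k_{jj} L)^2} from the principal radii of gyration.
#' Radii of gyration are floored at 1e-6 so the tensor stays positive
#' definite even for degenerate table entries.
#'
#' @param table an [anthropometric_table()].
#' @param segment segment name (without side prefix), e.g. `"thigh"`.
#' @param length segment length (m, > 0).
#' @param body_mass subject mass (kg, > 0).
#' @return list with `mass` (kg), `com_fraction`, `inertia` (3 x 3, kg m^2,
#'   local principal axes at the segment COM).
#' @export
segment_inertia <- function(table, segment, length, body_mass) {
  stopifnot(inherits(table, "anthropometric_table"))
  if (length <= 0 || body_mass <= 0) stop("length and body_mass must be positive")
  s <- table[[segment]]
  if (is.null(s)) stop("unknown segment '", segment, "'")
  m <- s$mass_fraction * body_mass
  k <- pmax(unlist(s$gyration), 1e-6)
  list(mass = m,
       com_fraction = s$com_fraction,
       inertia = diag(m * (k * length)^2))
}
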
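#' Anatomical parameters of a synthetic thoracic aorta
#'
#' Parameterizes one swept-tube thoracic aorta: a straight ascending segment,
#' a circular-arc arch with an optional out-of-plane (torsional) perturbation,
#' a straight descending segment, and the three supra-aortic branches (BCA,
#' LCCA, LSA) emanating from the arch. Default values are chosen so that the
#' template tract lengths and radii fall in the range reported for healthy
#' adult thoracic aortas (ascending tract ~90 mm, arch ~38 mm, descending
#' ~125 mm, root radius 16 mm tapering to ~12 mm, supra-aortic radii
#' 6.3/3.4/5.3 mm).
#'
#' @param ascending_length length of the straight ascending segment, mm.
#' @param arch_radius radius of the arch's guiding circular arc, mm.
#' @param arch_angle angular span of the arch, radians; must lie in
#'   (pi/2, 3*pi/2).
#' @param descending_length length of the straight descending segment, mm.
#' @param root_radius lumen radius at the aortic root, mm.
#' @param taper_ratio descending-end radius divided by root radius
#'   (dimensionless); the lumen radius tapers linearly along the vessel.
#' @param torsion_amplitude amplitude of the out-of-plane sinusoidal
#'   displacement of the arch, mm (0 gives a planar arch).
#' @param branch_origin_u arc-length fractions in (0, 1) along the arch at
#'   which the BCA, LCCA and LSA ostia sit; strictly increasing.
#' @param branch_radii lumen radii of BCA, LCCA, LSA, mm.
#' @param branch_lengths lengths of BCA, LCCA, LSA, mm.
#' @param bovine_arch logical; when `TRUE` the BCA and LCCA share a common
#'   origin (bovine-arch variant) with a short common trunk.
#' @param bovine_trunk_length length of the shared BCA/LCCA trunk in the
#'   bovine variant, mm.
#'
#' @return An object of class `aorta_params` (a named list).
#' @seealso [build_geometry()], [population_spec()]
#' @export
#' @examples
#' p <- aorta_params(torsion_amplitude = 0)
#' p$arch_angle
aorta_params <- function(ascending_length = 70,
                         arch_radius = 28,
                         arch_angle = pi,
                         descending_length = 95,
                         root_radius = 16,
                         taper_ratio = 0.73,
                         torsion_amplitude = 5,
                         branch_origin_u = c(bca = 0.25, lcca = 0.45, lsa = 0.65),
                         branch_radii = c(bca = 6.3, lcca = 3.4, lsa = 5.3),
                         branch_lengths = c(bca = 42, lcca = 40, lsa = 40),
                         bovine_arch = FALSE,
                         bovine_trunk_length = 8) {
  p <- structure(
    list(
      ascending_length = ascending_length,
      arch_radius = arch_radius,
      arch_angle = arch_angle,
      descending_length = descending_length,
      root_radius = root_radius,
      taper_ratio = taper_ratio,
      torsion_amplitude = torsion_amplitude,
      branch_origin_u = setNames(branch_origin_u, c("bca", "lcca", "lsa")),
      branch_radii = setNames(branch_radii, c("bca", "lcca", "lsa")),
      branch_lengths = setNames(branch_lengths, c("bca", "lcca", "lsa")),
      bovine_arch = isTRUE(bovine_arch),
      bovine_trunk_length = bovine_trunk_length
    ),
    class = "aorta_params"
  )
  validate_aorta_params(p)
}

#' Validate anatomical parameters
#'
#' Checks the `aorta_params` invariants (positivity, strictly increasing
#' branch origins, arch angle in (pi/2, 3*pi/2), branch radii smaller than the
#' root radius) and fails naming the offending field.
#'
#' @param p an [aorta_params()] object.
#' @return `p`, invisibly valid.
#' @export
validate_aorta_params <- function(p) {
  for (f in c("ascending_length", "arch_radius", "descending_length",
              "root_radius", "taper_ratio", "torsion_amplitude",
              "branch_radii", "branch_lengths", "bovine_trunk_length")) {
    v <- p[[f]]
    if (f == "torsion_amplitude") {
      if (!all(is.finite(v)) || any(v < 0)) {
        abort(sprintf("field '%s' must be finite and >= 0", f))
      }
    } else {
      stopifnot_positive(v, f)
    }
  }
  u <- p$branch_origin_u
  if (length(u) != 3 || any(!is.finite(u)) || any(u <= 0) || any(u >= 1)) {
    abort("field 'branch_origin_u' must hold 3 values in (0, 1)")
  }
  if (any(diff(u) <= 0)) {
    abort("field 'branch_origin_u' must be strictly increasing (BCA < LCCA < LSA)")
  }
  if (!is_scalar_number(p$arch_angle) ||
      p$arch_angle <= pi / 2 || p$arch_angle >= 3 * pi / 2) {
    abort("field 'arch_angle' must lie in (pi/2, 3*pi/2)")
  }
  if (any(p$branch_radii >= p$root_radius)) {
    abort("field 'branch_radii' must all be smaller than 'root_radius'")
  }
  invisible(p)
}

#' @export
print.aorta_params <- function(x, ...) {
  cat("<aorta_params>\n")
  cat(sprintf("  ascending %0.1f mm | arch R %0.1f mm over %0.2f rad | descending %0.1f mm\n",
              x$ascending_length, x$arch_radius, x$arch_angle, x$descending_length))
  cat(sprintf("  root radius %0.1f mm, taper %0.2f, torsion amplitude %0.1f mm\n",
              x$root_radius, x$taper_ratio, x$torsion_amplitude))
  cat(sprintf("  branch origins u = %s%s\n",
              paste(sprintf("%0.2f", x$branch_origin_u), collapse = ", "),
              if (x$bovine_arch) " (bovine arch)" else ""))
  invisible(x)
}

# Fields that are sampled per subject, with their default coefficients of
# variation. branch_origin_u uses a deliberately small CV so that +-3 sd
# truncation can never reorder the three ostia.
default_param_cv <- function() {
  list(
    ascending_length = 0.10,
    arch_radius = 0.09,
    arch_angle = 0.05,
    descending_length = 0.08,
    root_radius = 0.08,
    taper_ratio = 0.05,
    torsion_amplitude = 0.30,
    branch_origin_u = 0.05,
    branch_radii = 0.08,
    branch_lengths = 0.10
  )
}

#' Specification of a synthetic aortic population
#'
#' Describes how a corresponded population of synthetic thoracic aortas is
#' drawn: per-field truncated-normal variation (at +-3 coefficient of
#' variation) around mean anatomical parameters, plus a Bernoulli draw for
#' the bovine-arch variant. The default population size of 19 mirrors a
#' typical single-center healthy CT cohort.
#'
#' @param n_subjects number of subjects (>= 2), default 19.
#' @param means an [aorta_params()] object holding the per-field means.
#' @param cv named list of per-field coefficients of variation (>= 0);
#'   entries override [default_param_cv()].
#' @param bovine_arch_probability probability in \[0, 1\] that a subject has
#'   a bovine arch.
#' @param seed integer RNG seed; sampling is fully deterministic given it.
#'
#' @return An object of class `population_spec`.
#' @seealso [sample_population()]
#' @export
population_spec <- function(n_subjects = 19,
                            means = aorta_params(),
                            cv = list(),
                            bovine_arch_probability = 0.15,
                            seed = 1L) {
  if (!is_scalar_number(n_subjects) || n_subjects < 2) {
    abort("field 'n_subjects' must be >= 2")
  }
  validate_aorta_params(means)
  cvs <- modifyList(default_param_cv(), cv)
  bad <- names(keep(cvs, ~ !is_scalar_number(.x) || .x < 0))
  if (length(bad) > 0) {
    abort(sprintf("field 'cv$%s' must be a finite value >= 0", bad[[1]]))
  }
  if (!is_scalar_number(bovine_arch_probability) ||
      bovine_arch_probability < 0 || bovine_arch_probability > 1) {
    abort("field 'bovine_arch_probability' must lie in [0, 1]")
  }
  structure(
    list(
      n_subjects = as.integer(n_subjects),
      means = means,
      cv = cvs,
      bovine_arch_probability = bovine_arch_probability,
      seed = as.integer(seed)
    ),
    class = "population_spec"
  )
}

# Draw one subject's parameters; errors if truncation cannot keep them valid.
sample_aorta_params <- function(spec) {
  m <- spec$means
  cv <- spec$cv
  draw <- function(field) rnorm_trunc3(length(m[[field]]), m[[field]], cv[[field]])
  p <- m
  for (field in names(default_param_cv())) {
    v <- draw(field)
    names(v) <- names(m[[field]])
    p[[field]] <- v
  }
  p$bovine_arch <- runif(1) < spec$bovine_arch_probability
  tryCatch(
    validate_aorta_params(p),
    error = function(e) {
      abort(paste0(
        "population spec produced invalid parameters after +-3 CV truncation: ",
        conditionMessage(e)
      ))
    }
  )
  p
}

#' Sample a corresponded synthetic aortic population
#'
#' Draws `n_subjects` anatomies from a [population_spec()] and builds one
#' surface per subject with [build_geometry()]. All subjects share the same
#' ring/sample layout, so the population is point-corresponded by
#' construction: point `i` lies at the same parametric (ring, sample)
#' location on every subject.
#'
#' @param spec a [population_spec()].
#' @param resolution a [geometry_resolution()]; the default targets ~25,000
#'   surface points per subject.
#' @return A named list of [build_geometry()] objects (`aorta_geometry`),
#'   labeled `"subj01"`, `"subj02"`, ...
#' @export
#' @examples
#' pop <- sample_population(
#'   population_spec(n_subjects = 3, seed = 7),
#'   resolution = geometry_resolution(main_rings = 40, branch_rings = 8,
#'                                    ring_samples = 12)
#' )
#' length(pop)
sample_population <- function(spec, resolution = geometry_resolution()) {
  if (!inherits(spec, "population_spec")) abort("`spec` must be a population_spec")
  with_local_seed(spec$seed, {
    params <- map(seq_len(spec$n_subjects), ~ sample_aorta_params(spec))
  })
  labels <- sprintf("subj%02d", seq_len(spec$n_subjects))
  geoms <- map2(params, labels, function(p, lab) {
    build_geometry(p, resolution = resolution, label = lab)
  })
  setNames(geoms, labels)
}
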
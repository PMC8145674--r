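#' Model parameters for the membrane-adhesion lattice model
#'
#' Collects all physical and algorithmic constants of the two-membrane
#' lattice model: lattice geometry, effective bending rigidity, complex rest
#' lengths and binding windows, binding energies, species counts, the Monte
#' Carlo schedule and the random seed. All energies are dimensionless in
#' units of kBT, all lengths in nm, all times in MC steps (t0).
#'
#' The effective rigidity of the two apposing membranes with rigidities
#' `kappa1` and `kappa2` is `kappa = kappa1 * kappa2 / (kappa1 + kappa2)`;
#' pass either `kappa` directly or both `kappa1` and `kappa2`.
#'
#' @param nx,ny Number of lattice patches per side (default 100 x 100).
#' @param patch_size Linear patch size a in nm (default 15).
#' @param kappa Effective bending rigidity in kBT (default 20). Ignored if
#'   `kappa1` and `kappa2` are both given.
#' @param kappa1,kappa2 Optional per-membrane rigidities in kBT.
#' @param tcr_rest,tcr_halfwidth Rest length and binding-window half-width of
#'   TCR/peptide-MHC complexes in nm (defaults 15 and 0.5).
#' @param lfa_rest,lfa_halfwidth Rest length and half-width of LFA-1/ICAM-1
#'   complexes in nm (defaults 40 and 0.5).
#' @param u_self,u_foreign Binding energies of TCR/self-pMHC and
#'   TCR/foreign-pMHC complexes in kBT.
#' @param u_li Binding energy of LFA-1/ICAM-1 complexes in kBT (default 9.5,
#'   which yields a complex concentration of about 100 per square micron).
#' @param n_tcr,n_lfa Protein counts on membrane 1.
#' @param n_self,n_foreign,n_icam Protein counts on membrane 2.
#' @param sep_halfwidth Half-width of the uniform separation-move proposal in
#'   nm (default 0.5).
#' @param n_steps Trajectory length in MC steps (default 2e8).
#' @param equilibration Initial MC steps discarded from equilibrium averages
#'   (default 4e7).
#' @param sampling_interval Interval between recorded conformations in MC
#'   steps (default 2e5).
#' @param contact_threshold Separation below which a patch pair counts as
#'   close contact, in nm (default 20).
#' @param seed Integer random seed.
#'
#' @return An object of class `adhesion_params` (a validated named list).
#' @seealso [build_scenario()] for the study presets, [validate_parameters()].
#' @export
model_parameters <- function(nx = 100L, ny = 100L,
                             patch_size = 15,
                             kappa = 20, kappa1 = NULL, kappa2 = NULL,
                             tcr_rest = 15, tcr_halfwidth = 0.5,
                             lfa_rest = 40, lfa_halfwidth = 0.5,
                             u_self = 6, u_foreign = 12, u_li = 9.5,
                             n_tcr = 270L, n_lfa = 270L,
                             n_self = 270L, n_foreign = 0L, n_icam = 270L,
                             sep_halfwidth = 0.5,
                             n_steps = 2e8, equilibration = 4e7,
                             sampling_interval = 2e5,
                             contact_threshold = 20,
                             seed = 1L) {
  if (!is.null(kappa1) || !is.null(kappa2)) {
    if (is.null(kappa1) || is.null(kappa2))
      stop("give both `kappa1` and `kappa2`, or `kappa` alone")
    kappa <- effective_rigidity(kappa1, kappa2)
  }
  p <- list(
    nx = as.integer(nx), ny = as.integer(ny),
    patch_size = patch_size, kappa = kappa,
    tcr_rest = tcr_rest, tcr_halfwidth = tcr_halfwidth,
    lfa_rest = lfa_rest, lfa_halfwidth = lfa_halfwidth,
    u_self = u_self, u_foreign = u_foreign, u_li = u_li,
    n_tcr = as.integer(n_tcr), n_lfa = as.integer(n_lfa),
    n_self = as.integer(n_self), n_foreign = as.integer(n_foreign),
    n_icam = as.integer(n_icam),
    sep_halfwidth = sep_halfwidth,
    n_steps = n_steps, equilibration = equilibration,
    sampling_interval = sampling_interval,
    contact_threshold = contact_threshold,
    seed = as.integer(seed)
  )
  class(p) <- "adhesion_params"
  validate_parameters(p)
  p
}

#' Validate a parameter set
#'
#' Checks positivity of all lengths, that the binding-window half-widths are
#' smaller than the rest lengths, that the TCR/pMHC and LFA-1/ICAM-1 binding
#' windows are disjoint, and that the species counts fit on each membrane.
#'
#' @param p An `adhesion_params` object.
#' @return `p`, invisibly; errors if any invariant is violated.
#' @export
validate_parameters <- function(p) {
  stopifnot(inherits(p, "adhesion_params"))
  lens <- c(p$patch_size, p$tcr_rest, p$lfa_rest, p$contact_threshold)
  if (any(lens <= 0)) stop("all lengths must be positive")
  if (p$nx < 1L || p$ny < 1L) stop("lattice dimensions must be >= 1")
  if (p$kappa <= 0) stop("bending rigidity must be positive")
  if (p$tcr_halfwidth <= 0 || p$tcr_halfwidth >= p$tcr_rest)
    stop("TCR/pMHC half-width must lie in (0, rest length)")
  if (p$lfa_halfwidth <= 0 || p$lfa_halfwidth >= p$lfa_rest)
    stop("LFA-1/ICAM-1 half-width must lie in (0, rest length)")
  if (p$tcr_rest + p$tcr_halfwidth >= p$lfa_rest - p$lfa_halfwidth)
    stop("TCR/pMHC and LFA-1/ICAM-1 binding windows must be disjoint")
  n_patches <- p$nx * p$ny
  counts <- c(p$n_tcr, p$n_lfa, p$n_self, p$n_foreign, p$n_icam)
  if (any(counts < 0)) stop("species counts must be non-negative")
  if (p$n_tcr + p$n_lfa > n_patches)
    stop("membrane 1 holds more proteins than patches")
  if (p$n_self + p$n_foreign + p$n_icam > n_patches)
    stop("membrane 2 holds more proteins than patches")
  if (p$sep_halfwidth <= 0) stop("separation-move half-width must be positive")
  if (p$n_steps < 1 || p$equilibration < 0 || p$sampling_interval < 1)
    stop("invalid Monte Carlo schedule")
  invisible(p)
}

#' Effective bending rigidity of two apposing membranes
#'
#' `kappa1 * kappa2 / (kappa1 + kappa2)`, the rigidity of the effective
#' single-membrane description of the separation field.
#'
#' @param kappa1,kappa2 Membrane bending rigidities in kBT.
#' @return Effective rigidity in kBT.
#' @export
effective_rigidity <- function(kappa1, kappa2) {
  stopifnot(kappa1 > 0, kappa2 > 0)
  kappa1 * kappa2 / (kappa1 + kappa2)
}

#' Rest-length mismatch between the two complex types
#'
#' The length difference between LFA-1/ICAM-1 and TCR/peptide-MHC complexes
#' (25 nm at the default rest lengths of 40 and 15 nm), which drives the
#' curvature-mediated segregation of the two complex types.
#'
#' @param p An `adhesion_params` object.
#' @return Length mismatch in nm.
#' @export
length_mismatch <- function(p) {
  stopifnot(inherits(p, "adhesion_params"))
  p$lfa_rest - p$tcr_rest
}

#' Total projected membrane area
#'
#' @param p An `adhesion_params` object.
#' @param units `"nm2"` or `"um2"`.
#' @return Projected area of the simulated membrane segment.
#' @export
membrane_area <- function(p, units = c("um2", "nm2")) {
  units <- match.arg(units)
  area_nm2 <- p$nx * p$ny * p$patch_size^2
  if (units == "nm2") area_nm2 else area_nm2 * 1e-6
}

#' @export
print.adhesion_params <- function(x, ...) {
  cat("Membrane adhesion model parameters\n")
  cat(sprintf("  lattice: %d x %d patches of %g nm (%.4g um^2)\n",
              x$nx, x$ny, x$patch_size, membrane_area(x)))
  cat(sprintf("  kappa = %g kBT; windows %g+/-%g nm (TCR/pMHC), %g+/-%g nm (LFA-1/ICAM-1)\n",
              x$kappa, x$tcr_rest, x$tcr_halfwidth, x$lfa_rest, x$lfa_halfwidth))
  cat(sprintf("  U: self %g, foreign %g, LFA-1/ICAM-1 %g kBT\n",
              x$u_self, x$u_foreign, x$u_li))
  cat(sprintf("  counts: %d TCR + %d LFA-1 | %d self-pMHC + %d foreign-pMHC + %d ICAM-1\n",
              x$n_tcr, x$n_lfa, x$n_self, x$n_foreign, x$n_icam))
  cat(sprintf("  schedule: %g steps, %g equilibration, sample every %g t0, seed %d\n",
              x$n_steps, x$equilibration, x$sampling_interval, x$seed))
  invisible(x)
}

# keys allowed in configuration files, with unit annotations for writing
config_keys <- function() {
  c(nx = "patches", ny = "patches", patch_size = "nm", kappa = "kBT",
    tcr_rest = "nm", tcr_halfwidth = "nm", lfa_rest = "nm",
    lfa_halfwidth = "nm", u_self = "kBT", u_foreign = "kBT", u_li = "kBT",
    n_tcr = "count", n_lfa = "count", n_self = "count", n_foreign = "count",
    n_icam = "count", sep_halfwidth = "nm", n_steps = "t0",
    equilibration = "t0", sampling_interval = "t0",
    contact_threshold = "nm", seed = "integer")
}

#' Write a parameter set to a flat key=value configuration file
#'
#' @param p An `adhesion_params` object.
#' @param path File path to write.
#' @return `path`, invisibly.
#' @seealso [read_config()]
#' @export
write_config <- function(p, path) {
  validate_parameters(p)
  keys <- config_keys()
  lines <- c("# membrane adhesion model configuration",
             vapply(names(keys), function(k) {
               sprintf("%s=%.17g  # %s", k, as.numeric(p[[k]]), keys[[k]])
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a parameter set from a flat key=value configuration file
#'
#' Lines are `key=value`; `#` starts a comment. Keys not listed are filled
#' from the model defaults; unknown keys are an error.
#'
#' @param path File path to read.
#' @return An `adhesion_params` object.
#' @seealso [write_config()]
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- vapply(kv, length, 1L) != 2L
  if (any(bad)) stop("malformed configuration line: ", lines[bad][1])
  keys <- trimws(vapply(kv, `[`, character(1), 1L))
  vals <- trimws(vapply(kv, `[`, character(1), 2L))
  unknown <- setdiff(keys, names(config_keys()))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  if (anyDuplicated(keys)) stop("duplicated configuration key")
  args <- as.list(as.numeric(vals))
  names(args) <- keys
  do.call(model_parameters, args)
}
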
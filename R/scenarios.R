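# Scenario presets reproducing the three adhesion setups of the study, the
# six-run initial-condition protocol, and deterministic test fixtures.

.presets <- c("single_pmhc", "three_foreign", "one_foreign", "custom")

#' Build a scenario parameter set
#'
#' Three presets mirror the adhesion scenarios of the study on the full
#' 100 x 100 lattice (1.5 x 1.5 um^2, so 120 proteins per square micron per
#' species):
#' \describe{
#'   \item{single_pmhc}{270 TCR + 270 LFA-1 against 270 self-pMHC + 270
#'     ICAM-1; one peptide-MHC type with binding energy `u`.}
#'   \item{three_foreign}{as above but 3 foreign-pMHC + 267 self-pMHC.}
#'   \item{one_foreign}{1 foreign-pMHC + 269 self-pMHC.}
#'   \item{custom}{the plain defaults of [model_parameters()].}
#' }
#' A `scale` factor below 1 shrinks the lattice to `round(100 * scale)`
#' patches per side while preserving all areal densities (counts are rounded
#' to the nearest integer) and all energies; scaled presets are first-class
#' study conditions for desk-scale runs.
#'
#' @param preset Preset name.
#' @param u Binding energy of TCR/pMHC complexes in the `single_pmhc`
#'   scenario (sets `u_self`), kBT.
#' @param scale Linear scale factor for reduced-size runs (default 1).
#' @param ... Overrides passed to [model_parameters()] (unknown names are an
#'   error there).
#' @return An `adhesion_params` object with attributes `preset`, `scale` and
#'   `densities` (per-species areal densities per square micron after
#'   rounding).
#' @export
build_scenario <- function(preset = .presets, u = NULL, scale = 1, ...) {
  preset <- match.arg(preset)
  stopifnot(scale > 0)
  nx <- as.integer(round(100 * scale))
  ny <- nx
  cnt <- function(n270) as.integer(round(n270 * nx * ny / 1e4))
  base <- switch(preset,
    single_pmhc = list(n_tcr = cnt(270), n_lfa = cnt(270),
                       n_self = cnt(270), n_foreign = 0L,
                       n_icam = cnt(270)),
    three_foreign = list(n_tcr = cnt(270), n_lfa = cnt(270),
                         n_self = cnt(267), n_foreign = max(1L, cnt(3)),
                         n_icam = cnt(270)),
    one_foreign = list(n_tcr = cnt(270), n_lfa = cnt(270),
                       n_self = cnt(269), n_foreign = 1L,
                       n_icam = cnt(270)),
    custom = list())
  args <- c(list(nx = nx, ny = ny), base, list(...))
  if (!is.null(u)) {
    if (preset != "single_pmhc")
      stop("`u` names the single peptide-MHC binding energy; use `u_self` ",
           "and `u_foreign` for the two-type scenarios")
    args$u_self <- u
  }
  args <- args[!duplicated(names(args), fromLast = TRUE)]
  p <- do.call(model_parameters, args)
  attr(p, "preset") <- preset
  attr(p, "scale") <- scale
  area <- membrane_area(p, "um2")
  attr(p, "densities") <- c(TCR = p$n_tcr, LFA1 = p$n_lfa, SMHC = p$n_self,
                            FMHC = p$n_foreign, ICAM1 = p$n_icam) / area
  p
}

#' Six-run initial-condition protocol
#'
#' The study protocol runs six trajectories per parameter set from different
#' initial conformations: three with separations drawn uniformly from the
#' mixed intervals (14.5, 40.5), (13.5, 41.5), (12.5, 42.5) nm, in which
#' both complex types form from the start, and three from the narrow
#' intervals (39.5, 40.5), (38.5, 41.5), (37.5, 42.5) nm around the
#' LFA-1/ICAM-1 rest length, in which adhesion is initially mediated only by
#' LFA-1/ICAM-1 complexes. Child seeds are derived deterministically from
#' the master seed and re-randomize both the separation field and the
#' protein placements of each run.
#'
#' @param p An `adhesion_params` object (only checked for validity).
#' @param master_seed Integer master seed.
#' @return Data frame with columns `run`, `lmin`, `lmax`, `seed`.
#' @export
six_run_protocol <- function(p, master_seed) {
  validate_parameters(p)
  intervals <- rbind(c(14.5, 40.5), c(13.5, 41.5), c(12.5, 42.5),
                     c(39.5, 40.5), c(38.5, 41.5), c(37.5, 42.5))
  data.frame(run = 1:6,
             lmin = intervals[, 1], lmax = intervals[, 2],
             seed = child_seed(master_seed, 1:6))
}

#' Derive a deterministic child seed from a master seed
#'
#' A fixed affine hash modulo the Mersenne prime 2^31 - 1; distinct indices
#' give distinct seeds and the result always fits in a 32-bit integer.
#'
#' @param master_seed Integer master seed.
#' @param k Child index (vectorized).
#' @return Integer seed(s) in `[1, 2^31 - 1]`.
#' @export
child_seed <- function(master_seed, k) {
  m <- 2147483647
  x <- (as.numeric(master_seed) %% m) * 48271 + as.numeric(k) * 40503
  as.integer(x %% m + 1)
}

#' Deterministic small states for tests and demonstrations
#'
#' Named fixtures:
#' \describe{
#'   \item{flat-15}{8 x 8 flat field at 15 nm with one TCR/self-pMHC pair
#'     apposed at (3, 3): exactly one bond.}
#'   \item{flat-40}{8 x 8 flat field at 40 nm with two LFA-1/ICAM-1 pairs
#'     apposed at (2, 2) and (6, 6): exactly two bonds.}
#'   \item{single-bump}{8 x 8 flat field at 40 nm with a +1 nm bump at
#'     (4, 4); bending energy 0.888... kBT at the default parameters.}
#'   \item{clamp-pair}{8 x 8 flat field at 15 nm with one TCR/self-pMHC
#'     pair at the centre, no other proteins.}
#' }
#'
#' @param id Fixture name.
#' @return A `membrane_state`.
#' @export
make_fixture <- function(id) {
  switch(id,
    "flat-15" = {
      s <- membrane_state(matrix(15, 8, 8))
      s <- place_protein(s, 1, 3, 3, "TCR")
      place_protein(s, 2, 3, 3, "SMHC")
    },
    "flat-40" = {
      s <- membrane_state(matrix(40, 8, 8))
      s <- place_protein(s, 1, 2, 2, "LFA1")
      s <- place_protein(s, 2, 2, 2, "ICAM1")
      s <- place_protein(s, 1, 6, 6, "LFA1")
      place_protein(s, 2, 6, 6, "ICAM1")
    },
    "single-bump" = {
      l <- matrix(40, 8, 8)
      l[4, 4] <- 41
      membrane_state(l)
    },
    "clamp-pair" = {
      s <- membrane_state(matrix(15, 8, 8))
      s <- place_protein(s, 1, 4, 4, "TCR")
      place_protein(s, 2, 4, 4, "SMHC")
    },
    stop("unknown fixture id: ", id))
}
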
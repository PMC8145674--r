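# Membrane state: separation field + single-occupancy protein placements.
#
# Occupancy matrices hold integer species codes; position (row, col) is
# 1-based and the apposing-patch pairing is by identical index (projected
# geometry, no lateral offset between the membranes).

# species codes per membrane
.m1_species <- c(TCR = 1L, LFA1 = 2L)
.m2_species <- c(SMHC = 1L, FMHC = 2L, ICAM1 = 3L)
.kind_names <- c("tcr_self", "tcr_foreign", "lfa_icam")

#' Construct a membrane state
#'
#' A state holds the continuous separation field `l` (nm) of the apposing
#' patch pairs on a periodic square lattice, and one occupancy matrix per
#' membrane. Membrane 1 (the T-cell membrane) holds TCR and LFA-1 proteins;
#' membrane 2 holds self-pMHC, foreign-pMHC and ICAM-1 proteins. At most one
#' protein per patch per membrane.
#'
#' @param l Numeric matrix of patch-pair separations in nm, all `>= 0`.
#' @param occ1 Integer matrix of membrane-1 species codes (0 empty, 1 TCR,
#'   2 LFA-1), same dimensions as `l`. Defaults to empty.
#' @param occ2 Integer matrix of membrane-2 species codes (0 empty, 1
#'   self-pMHC, 2 foreign-pMHC, 3 ICAM-1). Defaults to empty.
#' @param step Step counter in t0 (default 0).
#' @return An object of class `membrane_state`.
#' @export
membrane_state <- function(l, occ1 = NULL, occ2 = NULL, step = 0) {
  l <- as.matrix(l)
  if (is.null(occ1)) occ1 <- matrix(0L, nrow(l), ncol(l))
  if (is.null(occ2)) occ2 <- matrix(0L, nrow(l), ncol(l))
  storage.mode(occ1) <- "integer"
  storage.mode(occ2) <- "integer"
  s <- structure(list(l = l, occ1 = occ1, occ2 = occ2, step = step),
                 class = "membrane_state")
  validate_state(s)
  s
}

#' Validate a membrane state
#'
#' @param s A `membrane_state`.
#' @return `s`, invisibly; errors on negative separations, mismatched
#'   dimensions or unknown species codes.
#' @export
validate_state <- function(s) {
  stopifnot(inherits(s, "membrane_state"))
  if (!all(dim(s$occ1) == dim(s$l)) || !all(dim(s$occ2) == dim(s$l)))
    stop("occupancy matrices must match the field dimensions")
  if (any(s$l < 0)) stop("separations must be non-negative")
  if (!all(s$occ1 %in% c(0L, .m1_species)))
    stop("invalid species code on membrane 1")
  if (!all(s$occ2 %in% c(0L, .m2_species)))
    stop("invalid species code on membrane 2")
  invisible(s)
}

#' Count proteins per species in a state
#'
#' @param s A `membrane_state`.
#' @return Named integer vector (TCR, LFA1, SMHC, FMHC, ICAM1).
#' @export
species_counts <- function(s) {
  c(TCR = sum(s$occ1 == .m1_species[["TCR"]]),
    LFA1 = sum(s$occ1 == .m1_species[["LFA1"]]),
    SMHC = sum(s$occ2 == .m2_species[["SMHC"]]),
    FMHC = sum(s$occ2 == .m2_species[["FMHC"]]),
    ICAM1 = sum(s$occ2 == .m2_species[["ICAM1"]]))
}

#' @export
print.membrane_state <- function(x, ...) {
  cnt <- species_counts(x)
  cat(sprintf("Membrane state: %d x %d patches, step %g t0\n",
              nrow(x$l), ncol(x$l), x$step))
  cat(sprintf("  separation: %.2f-%.2f nm (mean %.2f)\n",
              min(x$l), max(x$l), mean(x$l)))
  cat("  proteins:", paste(names(cnt), cnt, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Four nearest neighbours of a lattice patch with periodic wrap
#'
#' @param rc Integer vector `c(row, col)`, 1-based.
#' @param dims Integer vector `c(nx, ny)` of lattice dimensions.
#' @return A 4 x 2 integer matrix of neighbour coordinates in the order
#'   up, down, left, right (rows wrap modulo `nx`, columns modulo `ny`).
#'   On degenerate lattices (a side of length < 3) wrapped neighbours repeat.
#' @export
lattice_neighbors <- function(rc, dims) {
  r <- rc[[1]]; c <- rc[[2]]
  nx <- dims[[1]]; ny <- dims[[2]]
  if (r < 1 || r > nx || c < 1 || c > ny) stop("patch index out of range")
  wrap <- function(i, n) ((i - 1) %% n) + 1
  cbind(row = wrap(c(r - 1, r + 1, r, r), nx),
        col = wrap(c(c, c, c - 1, c + 1), ny))
}

# complex kind implied by the two species at an apposing patch pair (or NA)
.pair_kind <- function(occ1, occ2) {
  k <- matrix(NA_integer_, nrow(occ1), ncol(occ1))
  k[occ1 == 1L & occ2 == 1L] <- 1L  # tcr_self
  k[occ1 == 1L & occ2 == 2L] <- 2L  # tcr_foreign
  k[occ1 == 2L & occ2 == 3L] <- 3L  # lfa_icam
  k
}

#' Apposing cognate partner pairs
#'
#' All patch positions where membrane 1 and membrane 2 hold cognate species
#' (TCR opposite a peptide-MHC, or LFA-1 opposite ICAM-1), independently of
#' the local separation. The number of rows is M, the pair count entering
#' the pair-move substep of the MC schedule.
#'
#' @param s A `membrane_state`.
#' @return Data frame with columns `row`, `col`, `kind` (one of
#'   `"tcr_self"`, `"tcr_foreign"`, `"lfa_icam"`).
#' @export
apposing_pairs <- function(s) {
  k <- .pair_kind(s$occ1, s$occ2)
  idx <- which(!is.na(k), arr.ind = TRUE)
  data.frame(row = idx[, 1], col = idx[, 2],
             kind = .kind_names[k[idx]], stringsAsFactors = FALSE)
}

#' Bound complexes derived from the configuration
#'
#' An apposing cognate pair is bound if and only if the local separation lies
#' inside the closed binding window of its complex type
#' (`tcr_rest +/- tcr_halfwidth` for TCR/pMHC, `lfa_rest +/- lfa_halfwidth`
#' for LFA-1/ICAM-1). Bonds are always derived from the configuration; the
#' engine's incremental bond cache is checked against this function in the
#' test suite.
#'
#' @param s A `membrane_state`.
#' @param p An `adhesion_params` object.
#' @return Data frame with columns `row`, `col`, `kind`, `separation`.
#' @export
bonds <- function(s, p) {
  ap <- apposing_pairs(s)
  if (nrow(ap) == 0L) return(cbind(ap, separation = numeric(0)))
  sep <- s$l[cbind(ap$row, ap$col)]
  lo <- ifelse(ap$kind == "lfa_icam", p$lfa_rest - p$lfa_halfwidth,
               p$tcr_rest - p$tcr_halfwidth)
  hi <- ifelse(ap$kind == "lfa_icam", p$lfa_rest + p$lfa_halfwidth,
               p$tcr_rest + p$tcr_halfwidth)
  keep <- sep >= lo & sep <= hi
  out <- ap[keep, , drop = FALSE]
  out$separation <- sep[keep]
  rownames(out) <- NULL
  out
}

#' Place a protein on a membrane patch
#'
#' @param s A `membrane_state`.
#' @param membrane 1 or 2.
#' @param row,col Patch coordinates (1-based).
#' @param species Species tag: `"TCR"` or `"LFA1"` on membrane 1; `"SMHC"`,
#'   `"FMHC"` or `"ICAM1"` on membrane 2.
#' @return The modified state. Errors if the patch is occupied.
#' @export
place_protein <- function(s, membrane, row, col, species) {
  occ <- if (membrane == 1) s$occ1 else s$occ2
  codes <- if (membrane == 1) .m1_species else .m2_species
  if (!species %in% names(codes))
    stop("species ", species, " cannot sit on membrane ", membrane)
  if (occ[row, col] != 0L) stop("patch already occupied")
  occ[row, col] <- codes[[species]]
  if (membrane == 1) s$occ1 <- occ else s$occ2 <- occ
  s
}

#' Random initial state following the study protocol
#'
#' Separations are drawn i.i.d. uniformly from `interval`; the proteins of
#' each membrane are placed uniformly at random on unoccupied patches.
#'
#' @param p An `adhesion_params` object (species counts and geometry).
#' @param interval Length-2 numeric `c(lmin, lmax)` in nm with
#'   `0 <= lmin <= lmax`. Equal endpoints give a flat field.
#' @param seed Optional integer seed for the placement RNG; the caller's
#'   R random state is left untouched when given.
#' @return A `membrane_state`.
#' @export
make_initial_state <- function(p, interval, seed = NULL) {
  validate_parameters(p)
  lmin <- interval[[1]]; lmax <- interval[[2]]
  if (lmin < 0 || lmax < lmin) stop("invalid separation interval")
  if (!is.null(seed)) {
    old <- get0(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  n <- p$nx * p$ny
  l <- matrix(if (lmax > lmin) stats::runif(n, lmin, lmax) else lmin,
              p$nx, p$ny)
  occ1 <- matrix(0L, p$nx, p$ny)
  occ2 <- matrix(0L, p$nx, p$ny)
  n1 <- p$n_tcr + p$n_lfa
  if (n1 > 0) {
    pos <- sample.int(n, n1)
    occ1[pos] <- rep(c(1L, 2L), c(p$n_tcr, p$n_lfa))
  }
  n2 <- p$n_self + p$n_foreign + p$n_icam
  if (n2 > 0) {
    pos <- sample.int(n, n2)
    occ2[pos] <- rep(c(1L, 2L, 3L), c(p$n_self, p$n_foreign, p$n_icam))
  }
  membrane_state(l, occ1, occ2, step = 0)
}

# ---------------------------------------------------------------------------
# snapshot files: plain-text, lossless at the printed precision

#' Write a membrane state to a plain-text snapshot file
#'
#' Format: header `key=value` lines (`nx`, `ny`, `patch_size`, `step`,
#' `rng_seed`), a `field:` section with nx rows of ny separations in nm
#' (8 significant digits), and a `proteins:` section with one record per
#' protein: `membrane row col tag` with tags TCR, LFA1, SMHC, FMHC, ICAM1
#' and 1-based coordinates.
#'
#' @param s A `membrane_state`.
#' @param path File path.
#' @param patch_size Patch size recorded in the header, nm.
#' @param rng_seed Seed identifier recorded in the header.
#' @return `path`, invisibly.
#' @seealso [read_snapshot()]
#' @export
write_snapshot <- function(s, path, patch_size = 15, rng_seed = 0L) {
  validate_state(s)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# synapsim membrane snapshot",
               sprintf("nx=%d", nrow(s$l)),
               sprintf("ny=%d", ncol(s$l)),
               sprintf("patch_size=%.17g", patch_size),
               sprintf("step=%.17g", s$step),
               sprintf("rng_seed=%d", as.integer(rng_seed)),
               "field:"), con)
  writeLines(apply(s$l, 1, function(r) paste(sprintf("%.8g", r),
                                             collapse = " ")), con)
  writeLines("proteins:", con)
  for (mem in 1:2) {
    occ <- if (mem == 1) s$occ1 else s$occ2
    tags <- if (mem == 1) names(.m1_species) else names(.m2_species)
    idx <- which(occ != 0L, arr.ind = TRUE)
    if (nrow(idx)) {
      ord <- order(idx[, 1], idx[, 2])
      idx <- idx[ord, , drop = FALSE]
      writeLines(sprintf("%d %d %d %s", mem, idx[, 1], idx[, 2],
                         tags[occ[idx]]), con)
    }
  }
  invisible(path)
}

#' Read a membrane state from a snapshot file
#'
#' @param path File path written by [write_snapshot()].
#' @return A `membrane_state` with attributes `patch_size` and `rng_seed`.
#' @export
read_snapshot <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  fpos <- match("field:", lines)
  ppos <- match("proteins:", lines)
  if (is.na(fpos) || is.na(ppos)) stop("malformed snapshot file")
  hdr <- strsplit(lines[seq_len(fpos - 1)], "=", fixed = TRUE)
  hv <- vapply(hdr, `[`, character(1), 2L)
  names(hv) <- vapply(hdr, `[`, character(1), 1L)
  nx <- as.integer(hv[["nx"]]); ny <- as.integer(hv[["ny"]])
  rows <- lines[(fpos + 1):(fpos + nx)]
  l <- do.call(rbind, lapply(rows, function(r)
    as.numeric(strsplit(trimws(r), "\\s+")[[1]])))
  if (!all(dim(l) == c(nx, ny))) stop("field block has wrong dimensions")
  occ1 <- matrix(0L, nx, ny); occ2 <- matrix(0L, nx, ny)
  prot <- lines[-seq_len(ppos)]
  prot <- prot[nzchar(trimws(prot))]
  for (ln in prot) {
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    mem <- as.integer(f[1]); r <- as.integer(f[2]); c <- as.integer(f[3])
    if (mem == 1L) occ1[r, c] <- .m1_species[[f[4]]]
    else occ2[r, c] <- .m2_species[[f[4]]]
  }
  s <- membrane_state(l, occ1, occ2, step = as.numeric(hv[["step"]]))
  attr(s, "patch_size") <- as.numeric(hv[["patch_size"]])
  attr(s, "rng_seed") <- as.integer(hv[["rng_seed"]])
  s
}
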
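# Energy terms: discretized bending energy of the separation field and the
# square-well binding energies of the complexes. All energies in kBT.

#' Discretized Laplacian of the separation field at one patch
#'
#' `l_i1 + l_i2 + l_i3 + l_i4 - 4 l_i` over the four periodic nearest
#' neighbours of patch i.
#'
#' @param l Separation field matrix, nm.
#' @param rc Patch coordinates `c(row, col)`, 1-based.
#' @return Laplacian in nm.
#' @export
local_laplacian <- function(l, rc) {
  nb <- lattice_neighbors(rc, dim(l))
  sum(l[nb]) - 4 * l[rc[[1]], rc[[2]]]
}

#' Discretized Laplacian at every patch
#'
#' Vectorized periodic five-point stencil over the whole field.
#'
#' @param l Separation field matrix, nm.
#' @return Matrix of Laplacian values, nm.
#' @export
laplacian_field <- function(l) {
  nx <- nrow(l); ny <- ncol(l)
  up <- l[c(nx, seq_len(nx - 1)), , drop = FALSE]
  down <- l[c(seq_len(nx)[-1], 1), , drop = FALSE]
  left <- l[, c(ny, seq_len(ny - 1)), drop = FALSE]
  right <- l[, c(seq_len(ny)[-1], 1), drop = FALSE]
  up + down + left + right - 4 * l
}

#' Total bending energy of the separation field
#'
#' The discretized effective bending energy
#' `E = kappa / (2 a^2) * sum_i (Laplacian_i)^2` of the two membranes in the
#' effective single-field description. Non-negative; zero exactly for a
#' constant field.
#'
#' @param l Separation field matrix, nm.
#' @param p An `adhesion_params` object (`kappa`, `patch_size`).
#' @return Bending energy in kBT.
#' @export
bending_energy <- function(l, p) {
  p$kappa / (2 * p$patch_size^2) * sum(laplacian_field(l)^2)
}

#' Bending-energy change of a local separation shift
#'
#' Exact energy difference for shifting `l[rc]` by `dl`, computed locally:
#' only the Laplacians of the shifted patch and its four neighbours change,
#' so a five-site update suffices (13-patch read footprint). Equals
#' `bending_energy(after) - bending_energy(before)` to machine precision,
#' including on degenerate lattices where wrapped neighbours coincide.
#'
#' @param l Separation field matrix, nm.
#' @param rc Patch coordinates `c(row, col)`, 1-based.
#' @param dl Proposed shift in nm.
#' @param p An `adhesion_params` object.
#' @return Energy change in kBT.
#' @export
delta_bending <- function(l, rc, dl, p) {
  i <- rc[[1]]; j <- rc[[2]]
  nb <- lattice_neighbors(rc, dim(l))
  aff <- unique(rbind(matrix(c(i, j), 1), nb))
  dE <- 0
  for (r in seq_len(nrow(aff))) {
    s <- aff[r, ]
    lb <- local_laplacian(l, s)
    snb <- lattice_neighbors(s, dim(l))
    cnt <- sum(snb[, 1] == i & snb[, 2] == j)
    dlap <- dl * cnt - if (s[[1]] == i && s[[2]] == j) 4 * dl else 0
    dE <- dE + (lb + dlap)^2 - lb^2
  }
  p$kappa / (2 * p$patch_size^2) * dE
}

#' Binding energy of a configuration
#'
#' The square-well sum `-(n_self * Us + n_foreign * Uf + n_li * U_li)` over
#' the bound complexes of the configuration.
#'
#' @param s A `membrane_state`.
#' @param p An `adhesion_params` object.
#' @return Binding energy in kBT (non-positive).
#' @export
binding_energy <- function(s, p) {
  b <- bonds(s, p)
  if (nrow(b) == 0L) return(0)
  u <- c(tcr_self = p$u_self, tcr_foreign = p$u_foreign, lfa_icam = p$u_li)
  -sum(u[b$kind])
}

#' Energy breakdown of a configuration
#'
#' @param s A `membrane_state`.
#' @param p An `adhesion_params` object.
#' @return List with `e_bend`, `e_bind` and `e_total`, all in kBT.
#' @export
total_energy <- function(s, p) {
  eb <- bending_energy(s$l, p)
  ei <- binding_energy(s, p)
  list(e_bend = eb, e_bind = ei, e_total = eb + ei)
}

#' Binding-energy change of a proposed move
#'
#' Computes the change in binding energy for one elementary move, as
#' `-U * (bonds formed) + U * (bonds broken)` summed over complex kinds,
#' by recomputing the derived bond set before and after the proposal.
#'
#' @param s A `membrane_state`.
#' @param p An `adhesion_params` object.
#' @param change A list describing the proposal:
#'   `list(type = "separation", rc = c(row, col), dl = ...)`,
#'   `list(type = "protein", membrane = 1, from = c(row, col), to = c(row, col))`,
#'   or `list(type = "pair", from = c(row, col), to = c(row, col))`.
#' @return Binding-energy change in kBT.
#' @export
binding_delta <- function(s, p, change) {
  after <- s
  if (change$type == "separation") {
    rc <- change$rc
    after$l[rc[[1]], rc[[2]]] <- after$l[rc[[1]], rc[[2]]] + change$dl
  } else if (change$type == "protein") {
    f <- change$from; t <- change$to
    occ <- if (change$membrane == 1) after$occ1 else after$occ2
    if (occ[t[[1]], t[[2]]] != 0L) stop("target patch occupied")
    occ[t[[1]], t[[2]]] <- occ[f[[1]], f[[2]]]
    occ[f[[1]], f[[2]]] <- 0L
    if (change$membrane == 1) after$occ1 <- occ else after$occ2 <- occ
  } else if (change$type == "pair") {
    f <- change$from; t <- change$to
    if (after$occ1[t[[1]], t[[2]]] != 0L || after$occ2[t[[1]], t[[2]]] != 0L)
      stop("target patches occupied")
    after$occ1[t[[1]], t[[2]]] <- after$occ1[f[[1]], f[[2]]]
    after$occ2[t[[1]], t[[2]]] <- after$occ2[f[[1]], f[[2]]]
    after$occ1[f[[1]], f[[2]]] <- 0L
    after$occ2[f[[1]], f[[2]]] <- 0L
  } else stop("unknown move type")
  binding_energy(after, p) - binding_energy(s, p)
}

#' Metropolis acceptance rule
#'
#' Accept with probability 1 for `dE <= 0` and with probability
#' `exp(-dE)` (energies in kBT) otherwise, decided against the supplied
#' uniform deviate.
#'
#' @param dE Energy change in kBT.
#' @param u Uniform deviate in `[0, 1)`.
#' @return Logical: accept the move?
#' @export
metropolis_accept <- function(dE, u) {
  stopifnot(u >= 0, u < 1)
  dE <= 0 || u < exp(-dE)
}
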
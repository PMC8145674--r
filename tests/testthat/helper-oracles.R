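# Independent reference implementations used as oracles. These deliberately
# share no code with the package: plain modular index arithmetic and
# explicit loops.

# Laplacian at (i, j) by direct periodic neighbour lookup
oracle_laplacian <- function(l, i, j) {
  nx <- nrow(l); ny <- ncol(l)
  w <- function(i, n) ((i - 1) %% n) + 1
  l[w(i - 1, nx), j] + l[w(i + 1, nx), j] +
    l[i, w(j - 1, ny)] + l[i, w(j + 1, ny)] - 4 * l[i, j]
}

# total bending energy by double loop over all patches
oracle_bending <- function(l, kappa, a) {
  e <- 0
  for (i in seq_len(nrow(l)))
    for (j in seq_len(ncol(l)))
      e <- e + oracle_laplacian(l, i, j)^2
  kappa / (2 * a^2) * e
}

# total binding energy by scanning every patch pair against the windows
oracle_binding <- function(st, p) {
  e <- 0
  for (i in seq_len(nrow(st$l))) {
    for (j in seq_len(ncol(st$l))) {
      s1 <- st$occ1[i, j]; s2 <- st$occ2[i, j]; sep <- st$l[i, j]
      if (s1 == 1L && s2 == 1L &&
          abs(sep - p$tcr_rest) <= p$tcr_halfwidth) e <- e - p$u_self
      if (s1 == 1L && s2 == 2L &&
          abs(sep - p$tcr_rest) <= p$tcr_halfwidth) e <- e - p$u_foreign
      if (s1 == 2L && s2 == 3L &&
          abs(sep - p$lfa_rest) <= p$lfa_halfwidth) e <- e - p$u_li
    }
  }
  e
}

oracle_total <- function(st, p) {
  oracle_bending(st$l, p$kappa, p$patch_size) + oracle_binding(st, p)
}

# contact-event segmentation by an explicit forward scan
oracle_segment <- function(contact, tcr) {
  events <- list()
  i <- 1L
  n <- length(contact)
  while (i <= n) {
    if (contact[i]) {
      j <- i
      while (j < n && contact[j + 1L]) j <- j + 1L
      events[[length(events) + 1L]] <-
        c(start = i, end = j, qualifying = any(tcr[i:j]))
      i <- j + 1L
    } else i <- i + 1L
  }
  if (!length(events))
    return(data.frame(start = integer(0), end = integer(0),
                      qualifying = logical(0)))
  out <- as.data.frame(do.call(rbind, events))
  out$qualifying <- as.logical(out$qualifying)
  out
}

# a disordered small state with every species present
random_test_state <- function(nx = 8, ny = 8, seed = 1) {
  set.seed(seed)
  l <- matrix(runif(nx * ny, 10, 45), nx, ny)
  st <- membrane_state(l)
  pos1 <- sample(nx * ny, 6)
  pos2 <- sample(nx * ny, 6)
  sp1 <- c("TCR", "TCR", "TCR", "LFA1", "LFA1", "LFA1")
  sp2 <- c("SMHC", "SMHC", "FMHC", "ICAM1", "ICAM1", "ICAM1")
  for (k in 1:6) {
    st <- place_protein(st, 1, (pos1[k] - 1) %% nx + 1,
                        (pos1[k] - 1) %/% nx + 1, sp1[k])
    st <- place_protein(st, 2, (pos2[k] - 1) %% nx + 1,
                        (pos2[k] - 1) %/% nx + 1, sp2[k])
  }
  st
}

test_params_small <- function(nx = 8, ny = 8, ...) {
  args <- list(nx = nx, ny = ny, n_tcr = 3, n_lfa = 3, n_self = 2,
               n_foreign = 1, n_icam = 3, u_self = 5.9, u_foreign = 12)
  args <- utils::modifyList(args, list(...))
  do.call(model_parameters, args)
}
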
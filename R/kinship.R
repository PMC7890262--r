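#' Pedigree numerator relationship matrix (tabular method)
#'
#' Computes expected additive relationships by the recursive tabular method:
#' `A[i,i] = 1 + 0.5 A[sire, dam]` and `A[i,j] = 0.5 (A[j, sire(i)] +
#' A[j, dam(i)])`, processing animals in an order where parents precede
#' offspring.  Unknown parents (`NA`, `0`, or `""`) contribute zero.
#'
#' @param ped Data frame with columns `animal`, `sire`, `dam`; identifiers
#'   are arbitrary, unknown parents coded `NA`, `0` or blank.
#' @return Symmetric numeric matrix with `dimnames` the animal ids, in
#'   pedigree-sorted (parents-first) order.
#' @export
a_matrix <- function(ped) {
  ped <- normalize_pedigree(ped)
  ord <- pedigree_order(ped)
  id <- ped$animal[ord]
  si <- match(ped$sire[ord], id)
  di <- match(ped$dam[ord], id)
  n <- length(id)
  A <- matrix(0, n, n, dimnames = list(id, id))
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      aij <- 0.5 * ((if (is.na(s)) 0 else A[j, s]) +
                    (if (is.na(d)) 0 else A[j, d]))
      A[j, i] <- aij
      A[i, j] <- aij
    }
    A[i, i] <- 1 + 0.5 * (if (is.na(s) || is.na(d)) 0 else A[s, d])
  }
  A
}

# canonicalize unknown-parent codes and basic checks
normalize_pedigree <- function(ped) {
  for (cn in c("animal", "sire", "dam")) {
    if (!cn %in% names(ped)) stop("pedigree lacks column ", cn)
  }
  clean <- function(x) {
    x <- as.character(x)
    x[is.na(x) | x == "0" | trimws(x) == ""] <- NA_character_
    x
  }
  out <- data.frame(animal = as.character(ped$animal),
                    sire = clean(ped$sire), dam = clean(ped$dam),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$animal)) {
    stop("duplicate animal id(s) in pedigree: ",
         paste(unique(out$animal[duplicated(out$animal)]), collapse = ", "))
  }
  # parents appearing without their own record become founders
  extra <- setdiff(stats::na.omit(c(out$sire, out$dam)), out$animal)
  if (length(extra)) {
    out <- rbind(data.frame(animal = extra, sire = NA_character_,
                            dam = NA_character_, stringsAsFactors = FALSE),
                 out)
  }
  out
}

# topological sort (parents first); errors on cycles naming a member
pedigree_order <- function(ped) {
  n <- nrow(ped)
  si <- match(ped$sire, ped$animal)
  di <- match(ped$dam, ped$animal)
  depth <- rep(NA_integer_, n)
  calc <- function(i, stack) {
    if (!is.na(depth[i])) return(depth[i])
    if (i %in% stack) {
      stop("pedigree cycle involving animal ", ped$animal[i])
    }
    stack <- c(stack, i)
    ds <- if (is.na(si[i])) 0L else calc(si[i], stack)
    dd <- if (is.na(di[i])) 0L else calc(di[i], stack)
    depth[i] <<- max(ds, dd) + 1L
    depth[i]
  }
  for (i in seq_len(n)) calc(i, integer())
  order(depth, seq_len(n))
}

#' Genomic relationship matrix (VanRaden method 1)
#'
#' Centers allele dosages by twice the allele frequency estimated from the
#' genotyped set and scales by the expected heterozygosity sum:
#' `G = Z Z' / (2 sum p (1 - p))`.  Monomorphic markers are dropped with a
#' message; missing dosages are imputed to their column mean `2 p`.
#'
#' @param markers Numeric matrix of 0/1/2 allele dosages (rows = genotyped
#'   animals with rownames as ids, columns = markers); `NA` allowed.
#' @return Symmetric genomic relationship matrix over the genotyped animals.
#' @export
g_matrix <- function(markers) {
  M <- as.matrix(markers)
  if (is.null(rownames(M))) stop("marker matrix needs animal ids as rownames")
  rng <- base::range(M, na.rm = TRUE)
  if (rng[1L] < 0 || rng[2L] > 2) stop("allele dosages must lie in {0, 1, 2}")
  p <- colMeans(M, na.rm = TRUE) / 2
  poly <- p > 0 & p < 1 & !is.na(p)
  if (!any(poly)) stop("all markers are monomorphic")
  if (any(!poly)) {
    message("g_matrix: dropped ", sum(!poly), " monomorphic marker(s)")
  }
  M <- M[, poly, drop = FALSE]
  p <- p[poly]
  if (ncol(M) < 2L) stop("need at least 2 polymorphic markers")
  Z <- sweep(M, 2L, 2 * p)
  if (anyNA(Z)) Z[is.na(Z)] <- 0  # missing dosage -> 2p after centering
  tcrossprod(Z) / (2 * sum(p * (1 - p)))
}

#' Single-step blended relationship matrix (H)
#'
#' Combines the pedigree relationship matrix `A` (all animals) with a
#' genomic matrix `G` (genotyped subset) by the standard single-step
#' identity.  `G` is first affinely rescaled so its mean diagonal and mean
#' off-diagonal match the genotyped block `A22`, then blended as
#' `G* = (1 - blend_w) G_scaled + blend_w A22`.  With `blend_w = 1` or an
#' empty genotyped set, `H` reduces to `A`.
#'
#' @param A Pedigree relationship matrix with id dimnames.
#' @param G Genomic relationship matrix over the genotyped ids.
#' @param genotyped Character vector of genotyped ids (default
#'   `rownames(G)`); must be a subset of `rownames(A)`.
#' @param blend_w Weight on `A22` in the blend, in `[0, 1]` (default 0.05).
#' @param scale_g If `TRUE` (default), apply the mean diagonal/off-diagonal
#'   rescaling of `G` to `A22`.
#' @return Symmetric matrix over all ids of `A`, in `A`'s order.
#' @export
h_matrix <- function(A, G = NULL, genotyped = rownames(G), blend_w = 0.05,
                     scale_g = TRUE) {
  if (blend_w < 0 || blend_w > 1) stop("blend_w must lie in [0, 1]")
  ids <- rownames(A)
  if (is.null(ids)) stop("A needs id dimnames")
  if (length(genotyped) == 0L || blend_w == 1) return(A)
  if (!all(genotyped %in% ids)) {
    stop("genotyped id(s) absent from A: ",
         paste(setdiff(genotyped, ids), collapse = ", "))
  }
  G <- G[genotyped, genotyped, drop = FALSE]
  g2 <- match(genotyped, ids)
  g1 <- setdiff(seq_along(ids), g2)
  A22 <- A[g2, g2, drop = FALSE]

  if (scale_g && length(genotyped) > 1L) {
    off <- row(A22) != col(A22)
    mdA <- mean(diag(A22)); moA <- mean(A22[off])
    mdG <- mean(diag(G));   moG <- mean(G[off])
    b <- (mdA - moA) / (mdG - moG)
    a <- moA - b * moG
    G <- a + b * G
  }
  Gs <- (1 - blend_w) * G + blend_w * A22

  A22inv <- tryCatch(solve(A22), error = function(e) {
    stop("A22 is singular; consider a larger blend_w or pruning duplicates")
  })
  H <- A
  if (length(g1)) {
    A12 <- A[g1, g2, drop = FALSE]
    P <- A12 %*% A22inv           # n1 x n2
    D <- Gs - A22
    H[g1, g2] <- P %*% Gs
    H[g2, g1] <- t(H[g1, g2])
    H[g1, g1] <- A[g1, g1] + P %*% D %*% t(P)
  }
  H[g2, g2] <- Gs
  (H + t(H)) / 2
}

#' Sire block of a relationship matrix
#'
#' Principal submatrix restricted to the listed sires, in the given order.
#' Marginalization of a jointly Gaussian vector to a subset is exact, so
#' this block is the among-sire covariance kernel for the random-regression
#' sire model.
#'
#' @param H Relationship matrix with id dimnames.
#' @param sires Character vector of sire ids.
#' @return `length(sires)` square symmetric matrix.
#' @export
sire_block <- function(H, sires) {
  sires <- as.character(sires)
  miss <- setdiff(sires, rownames(H))
  if (length(miss)) {
    stop("sire id(s) absent from relationship matrix: ",
         paste(miss, collapse = ", "))
  }
  H[sires, sires, drop = FALSE]
}
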
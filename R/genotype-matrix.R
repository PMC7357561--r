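#' Diploid microsatellite genotype matrix
#'
#' A `genotype_matrix` holds diploid allele calls (positive integers: repeat
#' counts or fragment sizes) for a set of individuals typed at a set of
#' microsatellite loci, together with per-individual metadata (sex, locality,
#' optional coordinates). A genotype is either fully called (both allele
#' slots set) or missing (`NA` in both slots); partial calls are not
#' retained, matching the GENEPOP convention where a "0000" slot voids the
#' genotype.
#'
#' @param ids character vector of unique individual identifiers.
#' @param loci character vector of locus names.
#' @param a1,a2 integer matrices (individuals x loci) holding the two allele
#'   slots; `NA` marks missing genotypes and must coincide between the two.
#' @param sex factor/character vector with levels `"F"`, `"M"`, `"unknown"`;
#'   recycled `"unknown"` by default.
#' @param locality character vector of locality labels; default `"Pop1"`.
#' @param lat,lon optional numeric vectors of decimal-degree coordinates.
#'
#' @return An object of class `genotype_matrix`: a list with elements `ind`
#'   (data frame of metadata), `loci`, and allele matrices `a1`, `a2`.
#' @examples
#' gm <- genotype_matrix(
#'   ids = c("s1", "s2"), loci = c("L1", "L2"),
#'   a1 = matrix(c(10L, 10L, 7L, 8L), 2), a2 = matrix(c(12L, 10L, 7L, 8L), 2)
#' )
#' gm
#' @export
genotype_matrix <- function(ids, loci, a1, a2,
                            sex = NULL, locality = NULL,
                            lat = NULL, lon = NULL) {
  n <- length(ids)
  L <- length(loci)
  a1 <- matrix(as.integer(a1), n, L, dimnames = list(ids, loci))
  a2 <- matrix(as.integer(a2), n, L, dimnames = list(ids, loci))
  if (is.null(sex)) sex <- rep("unknown", n)
  if (is.null(locality)) locality <- rep("Pop1", n)
  ind <- data.frame(
    id = as.character(ids),
    sex = as.character(sex),
    locality = as.character(locality),
    lat = if (is.null(lat)) NA_real_ else as.numeric(lat),
    lon = if (is.null(lon)) NA_real_ else as.numeric(lon),
    stringsAsFactors = FALSE
  )
  gm <- structure(list(ind = ind, loci = as.character(loci), a1 = a1, a2 = a2),
                  class = "genotype_matrix")
  validate_genotype_matrix(gm)
}

#' Validate a genotype matrix
#'
#' Enforces the class invariants: unique ids, at least one individual and
#' locus, positive integer allele states, and a coherent missing pattern
#' (both slots `NA` or neither).
#'
#' @param gm a `genotype_matrix`.
#' @return `gm`, invisibly unchanged, or an error.
#' @export
validate_genotype_matrix <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  n <- nrow(gm$ind)
  L <- length(gm$loci)
  if (n < 1L) stop("genotype_matrix must contain at least one individual")
  if (L < 1L) stop("genotype_matrix must contain at least one locus")
  if (anyDuplicated(gm$ind$id))
    stop("duplicate individual id(s): ",
         paste(unique(gm$ind$id[duplicated(gm$ind$id)]), collapse = ", "))
  if (!all(dim(gm$a1) == c(n, L)) || !all(dim(gm$a2) == c(n, L)))
    stop("allele matrices must be individuals x loci")
  if (!identical(is.na(gm$a1), is.na(gm$a2)))
    stop("incoherent missing pattern: a genotype must be missing in both allele slots or neither")
  if (any(gm$a1 <= 0L, na.rm = TRUE) || any(gm$a2 <= 0L, na.rm = TRUE))
    stop("allele states must be positive integers")
  bad <- !gm$ind$sex %in% c("F", "M", "unknown")
  if (any(bad)) stop("sex must be one of F, M, unknown")
  gm
}

#' @export
print.genotype_matrix <- function(x, ...) {
  n <- nrow(x$ind)
  L <- length(x$loci)
  miss <- mean(is.na(x$a1))
  cat(sprintf("genotype_matrix: %d individuals x %d loci (%.1f%% missing)\n",
              n, L, 100 * miss))
  cat("localities:", paste(sprintf("%s (%d)", names(table(x$ind$locality)),
                                   table(x$ind$locality)), collapse = ", "), "\n")
  sx <- table(factor(x$ind$sex, c("F", "M", "unknown")))
  cat(sprintf("sex: %d F / %d M / %d unknown\n", sx[1], sx[2], sx[3]))
  invisible(x)
}

#' Number of individuals / loci helpers
#' @param gm a `genotype_matrix`.
#' @return integer count.
#' @export
n_individuals <- function(gm) nrow(gm$ind)

#' @rdname n_individuals
#' @export
n_loci <- function(gm) length(gm$loci)

#' Subset a genotype matrix by individuals and/or loci
#'
#' @param gm a `genotype_matrix`.
#' @param individuals logical/integer/character index into individuals.
#' @param loci logical/integer/character index into loci.
#' @return the subset `genotype_matrix`.
#' @export
subset_genotypes <- function(gm, individuals = NULL, loci = NULL) {
  if (is.null(individuals)) individuals <- seq_len(nrow(gm$ind))
  if (is.character(individuals)) individuals <- match(individuals, gm$ind$id)
  if (is.null(loci)) loci <- seq_along(gm$loci)
  if (is.character(loci)) loci <- match(loci, gm$loci)
  genotype_matrix(
    ids = gm$ind$id[individuals], loci = gm$loci[loci],
    a1 = gm$a1[individuals, loci, drop = FALSE],
    a2 = gm$a2[individuals, loci, drop = FALSE],
    sex = gm$ind$sex[individuals], locality = gm$ind$locality[individuals],
    lat = gm$ind$lat[individuals], lon = gm$ind$lon[individuals]
  )
}
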
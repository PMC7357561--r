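#' Locus definition for fragment-size to repeat-count conversion
#'
#' Microsatellite allele calls are often reported as fragment sizes in base
#' pairs. Converting to repeat counts requires the motif length and the
#' flanking-sequence offset: `repeat = (size - size_offset) / motif_length`.
#'
#' @param name locus name.
#' @param motif_length repeat-motif length in base pairs (>= 1).
#' @param size_offset flanking length in base pairs subtracted before
#'   division.
#' @return a `locus_def` list.
#' @export
locus_def <- function(name, motif_length = 1L, size_offset = 0L) {
  motif_length <- as.integer(motif_length)
  size_offset <- as.integer(size_offset)
  if (motif_length < 1L) stop("motif_length must be >= 1")
  structure(list(name = name, motif_length = motif_length,
                 size_offset = size_offset), class = "locus_def")
}

#' Convert allele calls from fragment sizes to repeat counts
#'
#' Applies `(size - size_offset) / motif_length` per locus, rounding to the
#' nearest integer. A call farther than `tolerance` repeat units from an
#' integer is off-ladder (dye shifts move whole ladders, not single
#' alleles) and raises an error naming the locus and individual. Idempotent
#' when calls are already repeat counts (`motif_length = 1`,
#' `size_offset = 0`).
#'
#' @param gm a [genotype_matrix()] with fragment-size calls.
#' @param defs list of [locus_def()]s covering every locus in `gm`.
#' @param tolerance maximum distance (repeat units) from an integer ladder
#'   position; default 0.25.
#' @return a [genotype_matrix()] on the repeat-count scale.
#' @export
to_repeat_units <- function(gm, defs, tolerance = 0.25) {
  nm <- vapply(defs, function(d) d$name, character(1))
  j <- match(gm$loci, nm)
  if (anyNA(j))
    stop("no locus_def for: ", paste(gm$loci[is.na(j)], collapse = ", "))
  for (l in seq_along(gm$loci)) {
    d <- defs[[j[l]]]
    for (slot in c("a1", "a2")) {
      x <- (gm[[slot]][, l] - d$size_offset) / d$motif_length
      r <- round(x)
      off <- which(abs(x - r) > tolerance & !is.na(x))
      if (length(off))
        stop("off-ladder allele(s) at locus ", gm$loci[l], ", individual(s) ",
             paste(gm$ind$id[off], collapse = ", "))
      gm[[slot]][, l] <- as.integer(r)
    }
  }
  validate_genotype_matrix(gm)
}

group_vector <- function(gm, grouping = c("pooled", "by_locality", "by_sex")) {
  grouping <- match.arg(grouping)
  switch(grouping,
    pooled = rep("all", nrow(gm$ind)),
    by_locality = gm$ind$locality,
    by_sex = gm$ind$sex
  )
}

#' Per-locus, per-group allele relative frequencies
#'
#' Counts gene copies among non-missing genotypes only; a (locus, group)
#' cell with no data is flagged absent (`NULL`) rather than zero-filled.
#'
#' @param gm a [genotype_matrix()].
#' @param grouping `"pooled"`, `"by_locality"`, or `"by_sex"`.
#' @return a `frequency_table`: list with `freq[[locus]][[group]]` (named
#'   numeric vectors summing to 1) and matching `n_genes[[locus]][[group]]`
#'   gene-copy counts.
#' @export
allele_frequencies <- function(gm,
                               grouping = c("pooled", "by_locality", "by_sex")) {
  grp <- group_vector(gm, grouping)
  groups <- unique(grp)
  freq <- list(); n_genes <- list()
  for (l in seq_along(gm$loci)) {
    fl <- list(); nl <- list()
    for (g in groups) {
      sel <- grp == g
      genes <- c(gm$a1[sel, l], gm$a2[sel, l])
      genes <- genes[!is.na(genes)]
      if (length(genes) == 0L) { fl[g] <- list(NULL); nl[[g]] <- 0L; next }
      tab <- table(genes)
      fl[[g]] <- as.numeric(tab) / length(genes)
      names(fl[[g]]) <- names(tab)
      nl[[g]] <- length(genes)
    }
    freq[[gm$loci[l]]] <- fl
    n_genes[[gm$loci[l]]] <- nl
  }
  structure(list(freq = freq, n_genes = n_genes, grouping = grouping),
            class = "frequency_table")
}

#' Per-locus polymorphism profile
#'
#' For each locus: `S` (individuals typed), `A` (distinct alleles among
#' non-missing calls), a polymorphic flag (`A >= 2`), and per-sex
#' polymorphism flags; plus the overall missing fraction (missing cells /
#' (individuals x loci)).
#'
#' @param gm a [genotype_matrix()].
#' @return list with a per-locus data frame `loci` and scalar
#'   `missing_fraction`.
#' @export
polymorphism_profile <- function(gm) {
  L <- length(gm$loci)
  res <- data.frame(
    locus = gm$loci, S = integer(L), A = integer(L),
    polymorphic = logical(L),
    polymorphic_F = NA, polymorphic_M = NA,
    stringsAsFactors = FALSE
  )
  for (l in seq_len(L)) {
    called <- !is.na(gm$a1[, l])
    res$S[l] <- sum(called)
    res$A[l] <- length(unique(c(gm$a1[called, l], gm$a2[called, l])))
    res$polymorphic[l] <- res$A[l] >= 2L
    for (sx in c("F", "M")) {
      sel <- called & gm$ind$sex == sx
      if (any(sel)) {
        res[[paste0("polymorphic_", sx)]][l] <-
          length(unique(c(gm$a1[sel, l], gm$a2[sel, l]))) >= 2L
      }
    }
  }
  list(loci = res, missing_fraction = mean(is.na(gm$a1)))
}
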
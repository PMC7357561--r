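#' Read diploid microsatellite genotypes
#'
#' Reads either the GENEPOP text format (title line, one locus name per line
#' or a comma-separated locus line, `POP` separators, then
#' `id , a1a2 a1a2 ...` rows with 2- or 3-digit allele coding, auto-detected)
#' or a delimited table with columns `id, sex, locality, lat, lon` followed
#' by two columns per locus named `<locus>_1` and `<locus>_2` (empty/NA =
#' missing).
#'
#' GENEPOP carries no locality names or sex; POP blocks are labelled
#' `Pop1..PopK` unless a sidecar metadata file (CSV with columns `id` and
#' any of `sex`, `locality`, `lat`, `lon`) is supplied.
#'
#' @param path path to the genotype file.
#' @param format `"genepop"` or `"table"`.
#' @param metadata optional path to a sidecar metadata CSV keyed by `id`.
#' @return a validated [genotype_matrix()].
#' @export
load_genotypes <- function(path, format = c("genepop", "table"),
                           metadata = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  gm <- switch(format,
    genepop = read_genepop(path),
    table = read_genotype_table(path)
  )
  if (!is.null(metadata)) gm <- apply_metadata(gm, metadata)
  gm
}

read_genepop <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\\s+$", "", lines)
  if (length(lines) < 3L || all(!nzchar(lines)))
    stop("parse error in ", path, ": empty or truncated GENEPOP file (line 1)")
  is_pop <- toupper(trimws(lines)) %in% c("POP")
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop) || first_pop < 3L)
    stop("parse error in ", path, ": no POP separator found or no locus list")
  # line 1 is the title; lines 2..(first_pop-1) are locus names, possibly
  # a single comma-separated line
  locus_lines <- lines[2:(first_pop - 1L)]
  loci <- trimws(unlist(strsplit(locus_lines, ",")))
  loci <- loci[nzchar(loci)]
  if (length(loci) == 0L)
    stop("parse error in ", path, ": empty locus list (line 2)")
  ids <- character(); pops <- character(); rows1 <- list(); rows2 <- list()
  pop_idx <- 0L
  for (i in seq(first_pop, length(lines))) {
    ln <- lines[i]
    if (!nzchar(trimws(ln))) next
    if (toupper(trimws(ln)) == "POP") { pop_idx <- pop_idx + 1L; next }
    parts <- strsplit(ln, ",")[[1]]
    if (length(parts) < 2L)
      stop("parse error in ", path, ": line ", i,
           " lacks the 'id , genotypes' comma")
    id <- trimws(parts[1])
    geno <- strsplit(trimws(paste(parts[-1], collapse = ",")), "\\s+")[[1]]
    geno <- geno[nzchar(geno)]
    if (length(geno) != length(loci))
      stop("ragged row in ", path, ": line ", i, " has ", length(geno),
           " genotypes for ", length(loci), " loci")
    w <- unique(nchar(geno))
    if (length(w) != 1L || !w %in% c(4L, 6L) || any(grepl("\\D", geno)))
      stop("parse error in ", path, ": line ", i,
           ": genotypes must be 4- or 6-digit numeric codes")
    half <- w / 2L
    x1 <- as.integer(substr(geno, 1L, half))
    x2 <- as.integer(substr(geno, half + 1L, w))
    miss <- x1 == 0L | x2 == 0L  # either slot 0 voids the genotype
    x1[miss] <- NA_integer_; x2[miss] <- NA_integer_
    ids <- c(ids, id)
    pops <- c(pops, sprintf("Pop%d", pop_idx))
    rows1[[length(rows1) + 1L]] <- x1
    rows2[[length(rows2) + 1L]] <- x2
  }
  if (length(ids) == 0L)
    stop("parse error in ", path, ": no individuals after first POP")
  genotype_matrix(
    ids = ids, loci = loci,
    a1 = do.call(rbind, rows1), a2 = do.call(rbind, rows2),
    locality = pops
  )
}

read_genotype_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(tab) == 0L) stop("parse error in ", path, ": empty table")
  need <- c("id", "sex", "locality", "lat", "lon")
  if (!all(need %in% names(tab)))
    stop("parse error in ", path, ": missing column(s) ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  geno_cols <- setdiff(names(tab), need)
  l1 <- grep("_1$", geno_cols, value = TRUE)
  loci <- sub("_1$", "", l1)
  if (length(loci) == 0L || !all(paste0(loci, "_2") %in% geno_cols))
    stop("parse error in ", path,
         ": genotype columns must come in <locus>_1/<locus>_2 pairs")
  a1 <- as.matrix(tab[paste0(loci, "_1")]); storage.mode(a1) <- "integer"
  a2 <- as.matrix(tab[paste0(loci, "_2")]); storage.mode(a2) <- "integer"
  miss <- is.na(a1) | is.na(a2)
  a1[miss] <- NA_integer_; a2[miss] <- NA_integer_
  sex <- ifelse(is.na(tab$sex) | !nzchar(tab$sex), "unknown", tab$sex)
  loc <- ifelse(is.na(tab$locality) | !nzchar(tab$locality), "Pop1",
                tab$locality)
  genotype_matrix(ids = tab$id, loci = loci, a1 = a1, a2 = a2,
                  sex = sex, locality = loc, lat = tab$lat, lon = tab$lon)
}

apply_metadata <- function(gm, metadata) {
  md <- utils::read.csv(metadata, stringsAsFactors = FALSE)
  if (!"id" %in% names(md)) stop("metadata file needs an 'id' column")
  j <- match(gm$ind$id, md$id)
  for (col in intersect(c("sex", "locality", "lat", "lon"), names(md))) {
    val <- md[[col]][j]
    keep <- !is.na(val)
    gm$ind[[col]][keep] <- val[keep]
  }
  validate_genotype_matrix(gm)
}

#' Write genotypes to GENEPOP or delimited-table format
#'
#' The written files round-trip exactly through [load_genotypes()]: allele
#' calls, missing pattern and (for the table format) all metadata are
#' preserved. GENEPOP output groups individuals into POP blocks by locality
#' (in order of first appearance) and uses 3-digit allele coding, or 2-digit
#' when all states fit.
#'
#' @param gm a [genotype_matrix()].
#' @param path output path.
#' @param format `"genepop"` or `"table"`.
#' @param title title line for GENEPOP output.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(gm, path, format = c("genepop", "table"),
                            title = "msatdemog export") {
  format <- match.arg(format)
  if (format == "table") {
    tab <- gm$ind
    ## full-precision coordinates so the table format round-trips exactly
    tab$lat <- sprintf("%.17g", tab$lat)
    tab$lon <- sprintf("%.17g", tab$lon)
    tab$lat[tab$lat == "NA"] <- NA
    tab$lon[tab$lon == "NA"] <- NA
    for (l in seq_along(gm$loci)) {
      tab[[paste0(gm$loci[l], "_1")]] <- gm$a1[, l]
      tab[[paste0(gm$loci[l], "_2")]] <- gm$a2[, l]
    }
    utils::write.csv(tab, path, row.names = FALSE, na = "")
    return(invisible(path))
  }
  digits <- if (max(gm$a1, gm$a2, 0L, na.rm = TRUE) < 100L) 2L else 3L
  if (max(gm$a1, gm$a2, 0L, na.rm = TRUE) >= 10^digits)
    stop("allele states exceed GENEPOP 3-digit coding")
  code <- function(x1, x2) {
    sprintf(paste0("%0", digits, "d%0", digits, "d"),
            ifelse(is.na(x1), 0L, x1), ifelse(is.na(x2), 0L, x2))
  }
  con <- file(path, "w"); on.exit(close(con))
  writeLines(title, con)
  writeLines(gm$loci, con)
  for (pop in unique(gm$ind$locality)) {
    writeLines("POP", con)
    for (i in which(gm$ind$locality == pop)) {
      writeLines(paste(gm$ind$id[i], ",",
                       paste(code(gm$a1[i, ], gm$a2[i, ]), collapse = " ")),
                 con)
    }
  }
  invisible(path)
}
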
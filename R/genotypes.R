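# Genotype tables for co-dominant microsatellite markers, ploidy 2 or 4.

#' Build a genotype table
#'
#' One row of `data` is one scored individual-locus record. Allele calls
#' sit in columns `allele_1` .. `allele_<ploidy>`; trailing blanks (`NA` or
#' `""`) mean the allele dosage could not be resolved (common for
#' tetraploids, where a partial heterozygote like {A, B} may hold any of
#' several dosages). Missing data are simply absent rows; sentinel alleles
#' are not allowed.
#'
#' @param data Data frame with columns `window`, `population`,
#'   `individual`, `locus`, `allele_1` .. `allele_k` (k <= ploidy).
#' @param ploidy 2 or 4.
#' @return An object of class `lg_genotypes`: a records tibble (one list
#'   column `alleles` of observed copies) plus the ploidy.
#' @export
genotype_table <- function(data, ploidy = 2L) {
  if (!ploidy %in% c(2L, 4L)) stop("ploidy must be 2 or 4", call. = FALSE)
  data <- tibble::as_tibble(data)
  need <- c("window", "population", "individual", "locus")
  if (!all(need %in% names(data)))
    stop("missing columns: ", paste(setdiff(need, names(data)), collapse = ", "),
         call. = FALSE)
  acols <- grep("^allele_[0-9]+$", names(data), value = TRUE)
  if (length(acols) == 0) stop("no allele_* columns found", call. = FALSE)
  if (length(acols) > ploidy)
    stop("more allele columns than the ploidy allows", call. = FALSE)
  am <- as.matrix(data[acols])
  am[am == ""] <- NA
  alleles <- lapply(seq_len(nrow(am)), function(i) {
    a <- am[i, ]
    as.character(a[!is.na(a)])
  })
  n_alleles <- lengths(alleles)
  if (any(n_alleles == 0))
    stop("records without any allele call; encode missing data as absent rows",
         call. = FALSE)
  rec <- tibble::tibble(window = as.character(data$window),
                        population = as.character(data$population),
                        individual = as.character(data$individual),
                        locus = as.character(data$locus),
                        alleles = alleles)
  key <- paste(rec$population, rec$individual, rec$locus, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (population, individual, locus) records", call. = FALSE)
  structure(list(records = rec, ploidy = as.integer(ploidy)),
            class = "lg_genotypes")
}

#' @export
print.lg_genotypes <- function(x, ...) {
  cat("<lg_genotypes> ploidy ", x$ploidy, ", ",
      length(unique(x$records$population)), " populations, ",
      length(unique(x$records$locus)), " loci, ",
      nrow(x$records), " records\n", sep = "")
  invisible(x)
}

#' Read a long-format genotype CSV
#'
#' @param path CSV with columns `window`, `population`, `individual`,
#'   `locus`, `allele_1` .. `allele_4` (blank cells for absent copies).
#' @param ploidy 2 or 4.
#' @return An `lg_genotypes` table.
#' @export
read_genotypes_csv <- function(path, ploidy = 2L) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  genotype_table(df, ploidy)
}

#' Import a GENEPOP file (read-only, 4-digit diploid)
#'
#' Parses the classic GENEPOP dialect: a title line, one locus name per
#' line (or one comma-separated line), `Pop` separators and individual
#' lines `name , 0101 0202 ...` with two 2-digit (or 3-digit) allele codes
#' per locus. `0000` codes missing data and becomes an absent record.
#'
#' @param path GENEPOP file.
#' @param window Window label assigned to all populations (GENEPOP has no
#'   window concept).
#' @return An `lg_genotypes` table with populations `pop_1`, `pop_2`, ...
#' @export
read_genepop <- function(path, window = "W1") {
  ln <- trimws(readLines(path, warn = FALSE))
  ln <- ln[nzchar(ln)]
  body <- ln[-1]
  pop_idx <- grep("^pop$", body, ignore.case = TRUE)
  if (length(pop_idx) == 0) stop("no 'Pop' line found", call. = FALSE)
  loci_lines <- body[seq_len(pop_idx[1] - 1L)]
  loci <- trimws(unlist(strsplit(loci_lines, ",")))
  loci <- loci[nzchar(loci)]
  rows <- list()
  pop_no <- 0L
  for (i in seq_along(body)) {
    if (grepl("^pop$", body[i], ignore.case = TRUE)) { pop_no <- pop_no + 1L; next }
    if (i <= pop_idx[1] - 1L) next
    parts <- strsplit(body[i], ",", fixed = TRUE)[[1]]
    if (length(parts) < 2) next
    ind <- trimws(parts[1])
    codes <- strsplit(trimws(paste(parts[-1], collapse = " ")), "\\s+")[[1]]
    if (length(codes) != length(loci))
      stop("individual ", ind, " has ", length(codes), " genotypes for ",
           length(loci), " loci", call. = FALSE)
    w <- nchar(codes[1]) / 2
    for (l in seq_along(loci)) {
      a1 <- substr(codes[l], 1, w)
      a2 <- substr(codes[l], w + 1, 2 * w)
      if (as.integer(a1) == 0 || as.integer(a2) == 0) next
      rows[[length(rows) + 1L]] <- tibble::tibble(
        window = window, population = paste0("pop_", pop_no),
        individual = ind, locus = loci[l], allele_1 = a1, allele_2 = a2)
    }
  }
  genotype_table(dplyr::bind_rows(rows), ploidy = 2L)
}
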
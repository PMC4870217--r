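#' Locus definitions for a microsatellite panel
#'
#' Builds the locus table used by [msat_dataset()]. Each locus has a repeat
#' motif length (2 or 3 bp for di-/trinucleotide repeats) and an optional
#' per-locus offset in bp that is subtracted from allele sizes before
#' conversion to repeat units (`(size - offset) / motif_length`).
#'
#' @param name character vector of locus names.
#' @param motif_length integer vector (2 or 3), recycled if length 1.
#' @param offset integer vector of per-locus bp offsets (default 0),
#'   recycled if length 1.
#' @param size_range optional 2-column matrix (or length-2 vector recycled)
#'   of valid allele-size bounds in bp.
#' @return data.frame with columns `name`, `motif_length`, `offset`,
#'   `size_min`, `size_max`.
#' @export
locus_def <- function(name, motif_length = 2L, offset = 0L, size_range = NULL) {
  name <- as.character(name)
  L <- length(name)
  if (anyDuplicated(name)) stop("duplicate locus names")
  motif_length <- as.integer(rep_len(motif_length, L))
  if (!all(motif_length %in% c(2L, 3L)))
    stop("motif_length must be 2 or 3")
  offset <- as.integer(rep_len(offset, L))
  if (is.null(size_range)) {
    size_min <- rep(NA_integer_, L); size_max <- rep(NA_integer_, L)
  } else {
    if (is.vector(size_range)) size_range <- matrix(size_range, L, 2, byrow = TRUE)
    if (any(size_range[, 1] >= size_range[, 2], na.rm = TRUE))
      stop("size_range: min must be < max")
    size_min <- as.integer(size_range[, 1]); size_max <- as.integer(size_range[, 2])
  }
  data.frame(name = name, motif_length = motif_length, offset = offset,
             size_min = size_min, size_max = size_max,
             stringsAsFactors = FALSE)
}

#' Diploid microsatellite dataset
#'
#' The central container of the package: allele-size calls (in base pairs)
#' for diploid individuals at a set of microsatellite loci, plus population
#' and (optionally) maternal-family labels and population metadata.
#'
#' @param alleles integer array of dimension `n x L x 2` of allele sizes in
#'   bp, `NA` for missing. Both gene copies at a locus must be present or
#'   both missing.
#' @param ind character vector of individual ids (length n).
#' @param pop character vector of population ids (length n).
#' @param loci locus table from [locus_def()] (L rows).
#' @param family optional character vector of mother/family ids.
#' @param meta optional population metadata data.frame as returned by
#'   [read_population_meta()]; if supplied, every population in `pop` must
#'   appear in `meta$population_id`.
#' @return object of class `msat_dataset`.
#' @export
msat_dataset <- function(alleles, ind, pop, loci, family = NULL, meta = NULL) {
  n <- length(ind)
  L <- nrow(loci)
  alleles <- array(as.integer(alleles), dim = c(n, L, 2),
                   dimnames = list(ind, loci$name, NULL))
  if (length(pop) != n) stop("pop must have one entry per individual")
  if (anyDuplicated(ind)) stop("duplicate individual ids")
  half <- is.na(alleles[, , 1, drop = FALSE]) != is.na(alleles[, , 2, drop = FALSE])
  if (any(half)) stop("half-missing genotypes: both calls must be present or both missing")
  if (is.null(family)) family <- rep(NA_character_, n)
  if (!is.null(meta)) {
    bad <- setdiff(unique(pop), meta$population_id)
    if (length(bad))
      stop("populations absent from meta: ", paste(bad, collapse = ", "))
  }
  structure(list(alleles = alleles, ind = as.character(ind),
                 pop = as.character(pop), family = as.character(family),
                 loci = loci, meta = meta),
            class = "msat_dataset")
}

#' @export
print.msat_dataset <- function(x, ...) {
  cat("msat_dataset:", length(x$ind), "individuals,",
      nrow(x$loci), "loci,", length(unique(x$pop)), "populations\n")
  miss <- mean(is.na(x$alleles[, , 1]))
  cat(sprintf("missing calls: %.1f%%\n", 100 * miss))
  invisible(x)
}

#' @export
summary.msat_dataset <- function(object, ...) {
  tab <- table(object$pop)
  cat("populations:\n")
  print(tab)
  cat("loci:", paste(object$loci$name, collapse = ", "), "\n")
  invisible(list(pop_sizes = tab, loci = object$loci))
}

#' Subset a dataset by individuals or populations
#'
#' @param dataset an [msat_dataset()].
#' @param ind character vector of individual ids to keep, or NULL.
#' @param pop character vector of population ids to keep, or NULL.
#' @return reduced `msat_dataset`.
#' @export
subset_dataset <- function(dataset, ind = NULL, pop = NULL) {
  keep <- rep(TRUE, length(dataset$ind))
  if (!is.null(ind)) keep <- keep & dataset$ind %in% ind
  if (!is.null(pop)) keep <- keep & dataset$pop %in% pop
  if (!any(keep)) stop("empty subset")
  msat_dataset(dataset$alleles[keep, , , drop = FALSE], dataset$ind[keep],
               dataset$pop[keep], dataset$loci,
               family = dataset$family[keep], meta = dataset$meta)
}

#' Allele sizes at one locus as a gene-copy matrix
#'
#' @param dataset an [msat_dataset()].
#' @param locus locus name or index.
#' @return integer matrix `n x 2` of sizes in bp (NA missing).
#' @export
locus_alleles <- function(dataset, locus) {
  dataset$alleles[, locus, , drop = TRUE]
}

#' Convert allele sizes to repeat units
#'
#' Applies the per-locus offset and motif length: `(size - offset) / motif`.
#' Non-integral repeat counts are allowed (fragment-size artefacts) but
#' flagged by [validate_dataset()].
#'
#' @param dataset an [msat_dataset()].
#' @return numeric array of repeat counts, same shape as `dataset$alleles`.
#' @export
repeat_units <- function(dataset) {
  L <- nrow(dataset$loci)
  out <- array(NA_real_, dim = dim(dataset$alleles), dimnames = dimnames(dataset$alleles))
  for (l in seq_len(L)) {
    out[, l, ] <- (dataset$alleles[, l, ] - dataset$loci$offset[l]) /
      dataset$loci$motif_length[l]
  }
  out
}

## ---- GENEPOP ----------------------------------------------------------

#' Read a GENEPOP file
#'
#' Accepts 2- or 3-digit allele coding, comma- or whitespace-separated
#' genotype fields, and `POP`-delimited population blocks. Populations are
#' named from the first individual label in each block (trailing commas and
#' trailing digits are stripped to form the population name when possible).
#'
#' @param path file path.
#' @param missing_code integer allele code treated as missing (default 0).
#' @param offset bp offset added to allele codes to obtain fragment sizes
#'   (default 0: codes are taken verbatim as bp sizes).
#' @param motif_length motif length(s) for the locus table (default 2).
#' @return an [msat_dataset()].
#' @export
read_genepop <- function(path, missing_code = 0L, offset = 0L, motif_length = 2L) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) < 3) stop("not a GENEPOP file: too short")
  # locus names: lines 2.. until first POP; may be comma-separated on one line
  ispop <- grepl("^\\s*pop\\s*$", lines, ignore.case = TRUE)
  first_pop <- which(ispop)[1]
  if (is.na(first_pop)) stop("not a GENEPOP file: no POP line")
  locus_lines <- lines[2:(first_pop - 1)]
  loci_names <- trimws(unlist(strsplit(paste(locus_lines, collapse = ","), ",")))
  loci_names <- loci_names[nzchar(loci_names)]
  L <- length(loci_names)
  pop_starts <- which(ispop)
  pop_ends <- c(pop_starts[-1] - 1, length(lines))
  ind <- character(); popv <- character(); rows <- list()
  for (b in seq_along(pop_starts)) {
    body <- lines[seq(pop_starts[b] + 1, pop_ends[b])]
    body <- body[!grepl("^\\s*$", body)]
    if (!length(body)) next
    pop_name <- NULL
    for (line in body) {
      parts <- strsplit(line, ",")[[1]]
      if (length(parts) < 2) stop("GENEPOP format error: no comma in line: ", line)
      id <- trimws(parts[1])
      geno <- trimws(paste(parts[-1], collapse = " "))
      fields <- strsplit(geno, "\\s+")[[1]]
      fields <- fields[nzchar(fields)]
      if (length(fields) != L)
        stop("GENEPOP format error: ", length(fields), " genotype fields for ",
             L, " loci (individual ", id, ")")
      wid <- unique(nchar(fields))
      if (length(wid) != 1 || !wid %in% c(4L, 6L))
        stop("GENEPOP format error: genotype strings must be 4 or 6 digits, got ",
             paste(wid, collapse = "/"))
      d <- wid / 2
      a1 <- as.integer(substr(fields, 1, d))
      a2 <- as.integer(substr(fields, d + 1, wid))
      if (anyNA(a1) || anyNA(a2)) stop("GENEPOP format error: non-numeric allele code")
      a1[a1 == missing_code] <- NA; a2[a2 == missing_code] <- NA
      miss <- is.na(a1) | is.na(a2)
      a1[miss] <- NA; a2[miss] <- NA
      if (is.null(pop_name)) {
        # population named from the first individual label of the block:
        # the part before the first underscore, else the label minus any
        # trailing digits
        pop_name <- if (grepl("_", id)) sub("_.*$", "", id)
        else sub("[0-9.-]+$", "", id)
        if (!nzchar(pop_name)) pop_name <- id
      }
      ind <- c(ind, id); popv <- c(popv, pop_name)
      rows[[length(rows) + 1]] <- cbind(a1, a2)
    }
  }
  n <- length(ind)
  alleles <- array(NA_integer_, dim = c(n, L, 2))
  for (i in seq_len(n)) {
    alleles[i, , 1] <- rows[[i]][, 1] + ifelse(is.na(rows[[i]][, 1]), 0L, offset)
    alleles[i, , 2] <- rows[[i]][, 2] + ifelse(is.na(rows[[i]][, 2]), 0L, offset)
  }
  if (anyDuplicated(ind)) ind <- make.unique(ind)
  msat_dataset(alleles, ind, popv, locus_def(loci_names, motif_length, offset = 0L))
}

#' Write a GENEPOP file
#'
#' Emits 3-digit coding by default; populations in metadata order (or first
#' appearance), individuals in input order.
#'
#' @param dataset an [msat_dataset()].
#' @param path output file path.
#' @param digits allele coding width per allele, 2 or 3 (default 3).
#' @param title header line (first line of the file).
#' @return `path`, invisibly.
#' @export
write_genepop <- function(dataset, path, digits = 3L, title = "msatabc export") {
  stopifnot(digits %in% c(2L, 3L))
  amax <- suppressWarnings(max(dataset$alleles, na.rm = TRUE))
  if (is.finite(amax) && amax > 10^digits - 1)
    stop("allele size ", amax, " not encodable with ", digits, "-digit coding")
  con <- file(path, "w"); on.exit(close(con))
  writeLines(title, con)
  writeLines(dataset$loci$name, con)
  pops <- if (!is.null(dataset$meta))
    intersect(dataset$meta$population_id, unique(dataset$pop)) else unique(dataset$pop)
  fmt <- paste0("%0", digits, "d")
  for (p in pops) {
    writeLines("POP", con)
    for (i in which(dataset$pop == p)) {
      g <- dataset$alleles[i, , , drop = TRUE]
      if (nrow(dataset$loci) == 1) g <- matrix(g, 1, 2)
      a1 <- ifelse(is.na(g[, 1]), 0L, g[, 1])
      a2 <- ifelse(is.na(g[, 2]), 0L, g[, 2])
      writeLines(paste0(dataset$ind[i], " ,  ",
                        paste0(sprintf(fmt, a1), sprintf(fmt, a2), collapse = " ")), con)
    }
  }
  invisible(path)
}

#' Read population metadata from CSV
#'
#' Expected columns: `population_id`, `lat`, `long`, `area`, `group`; extra
#' columns are carried through. Coordinates are validated (|lat| <= 90,
#' |long| <= 180) and grove areas must be positive.
#'
#' @param csv_path path to the CSV file.
#' @return data.frame with columns `population_id`, `latitude`, `longitude`,
#'   `grove_area`, `group_label` (plus any extras).
#' @export
read_population_meta <- function(csv_path) {
  df <- utils::read.csv(csv_path, stringsAsFactors = FALSE)
  if (nrow(df) == 0)
    return(data.frame(population_id = character(), latitude = numeric(),
                      longitude = numeric(), grove_area = numeric(),
                      group_label = character(), stringsAsFactors = FALSE))
  need <- c("population_id", "lat", "long", "area", "group")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$population_id))
    stop("duplicate population_id in metadata")
  lat <- suppressWarnings(as.numeric(df$lat))
  lon <- suppressWarnings(as.numeric(df$long))
  if (anyNA(lat) || anyNA(lon)) stop("non-numeric coordinate in metadata")
  if (any(abs(lat) > 90)) stop("latitude out of range [-90, 90]")
  if (any(abs(lon) > 180)) stop("longitude out of range [-180, 180]")
  area <- as.numeric(df$area)
  if (any(!is.finite(area) | area <= 0)) stop("grove_area must be positive")
  out <- data.frame(population_id = as.character(df$population_id),
                    latitude = lat, longitude = lon, grove_area = area,
                    group_label = as.character(df$group),
                    stringsAsFactors = FALSE)
  extra <- setdiff(names(df), need)
  for (nm in extra) out[[nm]] <- df[[nm]]
  out
}

#' Validate a dataset and report quality metrics
#'
#' Report-only: flags allele sizes not congruent with the locus motif length
#' after offset removal (possible scoring slippage), overall missing-call
#' fraction, and per-population sample sizes. Never modifies the dataset.
#'
#' @param dataset an [msat_dataset()].
#' @return list with `congruence_warnings` (data.frame locus/allele),
#'   `missing_fraction`, `pop_sizes`.
#' @export
validate_dataset <- function(dataset) {
  warns <- list()
  for (l in seq_len(nrow(dataset$loci))) {
    sizes <- unique(as.vector(dataset$alleles[, l, ]))
    sizes <- sizes[!is.na(sizes)]
    bad <- sizes[(sizes - dataset$loci$offset[l]) %% dataset$loci$motif_length[l] != 0]
    if (length(bad))
      warns[[length(warns) + 1]] <- data.frame(
        locus = dataset$loci$name[l], allele_bp = sort(bad))
  }
  congruence <- if (length(warns)) do.call(rbind, warns) else
    data.frame(locus = character(), allele_bp = integer())
  list(congruence_warnings = congruence,
       missing_fraction = mean(is.na(dataset$alleles[, , 1])),
       pop_sizes = table(dataset$pop))
}
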
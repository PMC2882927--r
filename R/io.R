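#' @useDynLib phylogap, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats var sd rnorm runif rpois rbinom rmultinom pbinom
#'   t.test complete.cases setNames cor quantile dist
#' @importFrom utils read.csv write.csv combn head
NULL

# ---------------------------------------------------------------------------
# Genotype matrix
# ---------------------------------------------------------------------------

#' Construct a diploid microsatellite genotype matrix
#'
#' Container for multilocus diploid genotypes with alleles coded as integer
#' repeat sizes.  Missing alleles are stored as \code{NA} (never zero), and
#' both allele matrices must be \code{NA} at the same positions per locus.
#'
#' @param individual_ids character vector, one per individual.
#' @param locality_ids character vector parallel to \code{individual_ids}.
#' @param loci character vector of locus names.
#' @param a1,a2 integer matrices (individuals x loci) holding the two
#'   alleles of each genotype; \code{NA} marks missing data.
#' @return An object of class \code{genotype_matrix}.
#' @export
genotype_matrix <- function(individual_ids, locality_ids, loci, a1, a2) {
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  storage.mode(a1) <- "integer"; storage.mode(a2) <- "integer"
  n <- length(individual_ids)
  if (length(locality_ids) != n)
    stop("locality_ids must parallel individual_ids")
  if (nrow(a1) != n || nrow(a2) != n || ncol(a1) != length(loci) ||
      ncol(a2) != length(loci))
    stop("allele matrices must be individuals x loci")
  if (!identical(unname(is.na(a1)), unname(is.na(a2))))
    stop("half-missing genotypes are not representable: a1/a2 NA patterns differ")
  dimnames(a1) <- dimnames(a2) <- list(individual_ids, loci)
  structure(list(individual_ids = as.character(individual_ids),
                 locality_ids = as.character(locality_ids),
                 loci = as.character(loci), a1 = a1, a2 = a2),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals, %d loci, %d localities\n",
              length(x$individual_ids), length(x$loci),
              length(unique(x$locality_ids))))
  miss <- mean(is.na(x$a1))
  cat(sprintf("  missing genotypes: %.1f%%\n", 100 * miss))
  invisible(x)
}

#' Number of individuals / loci
#' @param x a \code{genotype_matrix}.
#' @return integer count.
#' @export
n_individuals <- function(x) length(x$individual_ids)

#' @rdname n_individuals
#' @export
n_loci <- function(x) length(x$loci)

#' Read a diploid microsatellite genotype file
#'
#' Supports the two de-facto microsatellite interchange dialects:
#' \describe{
#'   \item{\code{structure_2row}}{STRUCTURE layout: an optional header row of
#'     locus names, then two rows per individual
#'     (\code{id locality allele...}).  Missing allele code \code{-9}.}
#'   \item{\code{genepop}}{Genepop: title line, locus names (one per line or
#'     comma-separated), \code{Pop} separators, individual lines
#'     \code{id , 6-digit genotypes} with 3-digit allele coding.
#'     \code{000} is missing.  The individual's locality is taken from the
#'     first id in its \code{Pop} block (Genepop convention).}
#' }
#'
#' @param path file to read.
#' @param dialect \code{"structure_2row"} or \code{"genepop"}.
#' @return a \code{\link{genotype_matrix}}.
#' @export
read_genotypes <- function(path, dialect = c("structure_2row", "genepop")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (dialect == "structure_2row") read_structure_2row(lines, path)
  else read_genepop(lines, path)
}

read_structure_2row <- function(lines, path) {
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty genotype file: ", path)
  toks <- strsplit(trimws(lines), "[ \t]+")
  # header = row whose tokens are all non-numeric
  has_header <- all(is.na(suppressWarnings(as.numeric(toks[[1]]))))
  first_data <- if (has_header) 2L else 1L
  data <- toks[first_data:length(toks)]
  if (length(data) %% 2L != 0L)
    stop("structure_2row: odd number of data rows in ", path)
  nl <- length(data[[1]]) - 2L
  if (nl < 1L) stop("structure_2row: line ", first_data,
                    " has no allele columns")
  loci <- if (has_header) toks[[1]] else paste0("L", seq_len(nl))
  if (length(loci) != nl)
    stop("structure_2row: header names ", length(loci),
         " loci but data rows have ", nl)
  nind <- length(data) %/% 2L
  ids <- locs <- character(nind)
  a1 <- a2 <- matrix(NA_integer_, nind, nl)
  for (i in seq_len(nind)) {
    r1 <- data[[2L * i - 1L]]; r2 <- data[[2L * i]]
    lineno <- first_data + 2L * i - 2L
    if (length(r1) != nl + 2L || length(r2) != nl + 2L)
      stop("structure_2row: line ", lineno, " of ", path,
           ": expected ", nl + 2L, " fields")
    if (r1[1] != r2[1])
      stop("structure_2row: line ", lineno, ": paired rows have ids '",
           r1[1], "' vs '", r2[1], "'")
    ids[i] <- r1[1]; locs[i] <- r1[2]
    v1 <- suppressWarnings(as.integer(r1[-(1:2)]))
    v2 <- suppressWarnings(as.integer(r2[-(1:2)]))
    if (anyNA(v1) || anyNA(v2))
      stop("structure_2row: line ", lineno, ": unknown allele token")
    v1[v1 == -9L] <- NA_integer_; v2[v2 == -9L] <- NA_integer_
    # a genotype is missing as a unit
    miss <- is.na(v1) | is.na(v2)
    v1[miss] <- NA_integer_; v2[miss] <- NA_integer_
    a1[i, ] <- v1; a2[i, ] <- v2
  }
  genotype_matrix(ids, locs, loci, a1, a2)
}

read_genepop <- function(lines, path) {
  if (length(lines) < 3L) stop("genepop: file too short: ", path)
  body <- lines[-1]                     # drop title
  pop_rows <- grep("^\\s*pop\\s*$", body, ignore.case = TRUE)
  if (!length(pop_rows)) stop("genepop: no 'Pop' line in ", path)
  locus_lines <- body[seq_len(pop_rows[1] - 1L)]
  loci <- trimws(unlist(strsplit(locus_lines, ",")))
  loci <- loci[nzchar(loci)]
  nl <- length(loci)
  ids <- locs <- character(0); rows1 <- rows2 <- list()
  pop_rows_ext <- c(pop_rows, length(body) + 1L)
  for (p in seq_along(pop_rows)) {
    blk <- body[seq(pop_rows_ext[p] + 1L, pop_rows_ext[p + 1L] - 1L)]
    blk <- blk[nzchar(trimws(blk))]
    pop_label <- NULL
    for (j in seq_along(blk)) {
      ln <- blk[j]
      lineno <- 1L + pop_rows_ext[p] + j   # position in original file
      parts <- strsplit(ln, ",")[[1]]
      if (length(parts) < 2L)
        stop("genepop: line ", lineno, " of ", path, ": missing ',' separator")
      id <- trimws(parts[1])
      gts <- strsplit(trimws(paste(parts[-1], collapse = ",")), "[ \t]+")[[1]]
      if (length(gts) != nl)
        stop("genepop: line ", lineno, ": expected ", nl,
             " genotypes, found ", length(gts))
      if (!all(grepl("^[0-9]{4}$|^[0-9]{6}$", gts)))
        stop("genepop: line ", lineno, ": unknown allele token")
      w <- nchar(gts[1]) %/% 2L
      v1 <- as.integer(substr(gts, 1L, w))
      v2 <- as.integer(substr(gts, w + 1L, 2L * w))
      v1[v1 == 0L] <- NA_integer_; v2[v2 == 0L] <- NA_integer_
      miss <- is.na(v1) | is.na(v2)
      v1[miss] <- NA_integer_; v2[miss] <- NA_integer_
      if (is.null(pop_label)) pop_label <- id
      ids <- c(ids, id); locs <- c(locs, pop_label)
      rows1[[length(rows1) + 1L]] <- v1; rows2[[length(rows2) + 1L]] <- v2
    }
  }
  genotype_matrix(ids, locs, loci, do.call(rbind, rows1), do.call(rbind, rows2))
}

#' Write genotypes in STRUCTURE two-row layout
#'
#' Inverse of \code{read_genotypes(dialect = "structure_2row")}; missing
#' alleles are written as \code{-9}.
#'
#' @param g a \code{\link{genotype_matrix}}.
#' @param path output file.
#' @export
write_genotypes <- function(g, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste(g$loci, collapse = "\t"), con)
  enc <- function(m) { m[is.na(m)] <- -9L; m }
  m1 <- enc(g$a1); m2 <- enc(g$a2)
  for (i in seq_along(g$individual_ids)) {
    writeLines(paste(c(g$individual_ids[i], g$locality_ids[i], m1[i, ]),
                     collapse = "\t"), con)
    writeLines(paste(c(g$individual_ids[i], g$locality_ids[i], m2[i, ]),
                     collapse = "\t"), con)
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# Sequence alignment
# ---------------------------------------------------------------------------

#' Construct an aligned set of haploid DNA sequences
#'
#' @param ids character vector of sequence names.
#' @param sequences character vector of equal-length strings over
#'   \code{A,C,G,T,N,-} (lowercase accepted and normalised).
#' @return object of class \code{seq_alignment} with fields \code{ids},
#'   \code{sequences}, \code{length}.
#' @export
seq_alignment <- function(ids, sequences) {
  sequences <- toupper(as.character(sequences))
  if (length(ids) != length(sequences)) stop("ids/sequences length mismatch")
  L <- unique(nchar(sequences))
  if (length(L) != 1L)
    stop("alignment error: sequences have unequal lengths (",
         paste(sort(L), collapse = ", "), ")")
  if (L == 0L) stop("alignment error: zero-length sequences")
  bad <- grepl("[^ACGTN-]", sequences)
  if (any(bad))
    stop("invalid characters in sequence(s): ",
         paste(ids[bad], collapse = ", "))
  structure(list(ids = as.character(ids), sequences = sequences, length = L),
            class = "seq_alignment")
}

#' @export
print.seq_alignment <- function(x, ...) {
  cat(sprintf("seq_alignment: %d sequences of %d sites\n",
              length(x$ids), x$length))
  invisible(x)
}

#' Read an aligned FASTA file
#'
#' Order-preserving; lowercase bases are normalised to uppercase; unequal
#' sequence lengths raise an alignment error.
#'
#' @param path FASTA file.
#' @return a \code{\link{seq_alignment}}.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- ape::read.FASTA(path)
  seq_alignment(names(d), vapply(as.character(d), paste, "", collapse = ""))
}

#' Write an alignment as FASTA
#' @param aln a \code{\link{seq_alignment}}.
#' @param path output file.
#' @export
write_fasta <- function(aln, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (i in seq_along(aln$ids))
    writeLines(c(paste0(">", aln$ids[i]), aln$sequences[i]), con)
  invisible(path)
}

#' Alignment as a character matrix (sequences x sites)
#' @param aln a \code{\link{seq_alignment}}.
#' @return character matrix with one row per sequence.
#' @export
alignment_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(aln$sequences, ""))
  rownames(m) <- aln$ids
  m
}

# ---------------------------------------------------------------------------
# Locality table
# ---------------------------------------------------------------------------

#' Read a locality table
#'
#' CSV with columns \code{locality_id}, \code{latitude}, \code{longitude}
#' and optionally \code{cluster}.
#'
#' @param path CSV file.
#' @return data.frame with validated coordinates and unique ids.
#' @export
read_localities <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("locality_id", "latitude", "longitude")
  if (!all(need %in% names(df)))
    stop("locality table must have columns: ", paste(need, collapse = ", "))
  validate_localities(df)
}

validate_localities <- function(df) {
  df$locality_id <- as.character(df$locality_id)
  if (anyDuplicated(df$locality_id))
    stop("duplicate locality_id in locality table")
  if (any(abs(df$latitude) > 90) || any(abs(df$longitude) > 180))
    stop("coordinates out of range")
  df
}

# ---------------------------------------------------------------------------
# ESRI ASCII grid rasters
# ---------------------------------------------------------------------------

#' Construct a georeferenced grid
#'
#' Values are stored as a numeric matrix with \code{nrows} rows; row 1 is
#' the top (northernmost) row, per the ESRI ASCII convention
#' (\code{xllcorner}/\code{yllcorner} give the lower-left corner of the
#' lower-left cell).  Nodata cells are stored as \code{NA}.
#'
#' @param values numeric matrix (nrows x ncols), \code{NA} = nodata.
#' @param xllcorner,yllcorner coordinates of the grid's lower-left corner.
#' @param cellsize cell edge length (grid units).
#' @param nodata_value sentinel written on output (default -9999).
#' @return object of class \code{asc_raster}.
#' @export
raster_grid <- function(values, xllcorner = 0, yllcorner = 0, cellsize = 1,
                        nodata_value = -9999) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  structure(list(ncols = ncol(values), nrows = nrow(values),
                 xllcorner = xllcorner, yllcorner = yllcorner,
                 cellsize = cellsize, nodata_value = nodata_value,
                 values = values),
            class = "asc_raster")
}

#' @export
print.asc_raster <- function(x, ...) {
  cat(sprintf("asc_raster: %d x %d cells, cellsize %g, %d nodata\n",
              x$nrows, x$ncols, x$cellsize, sum(is.na(x$values))))
  invisible(x)
}

#' Read an ESRI ASCII grid
#'
#' @param path \code{.asc} file: 6-line header (ncols, nrows, xllcorner,
#'   yllcorner, cellsize, NODATA_value) then whitespace-separated values in
#'   row-major order starting at the top-left cell.
#' @return an \code{\link{raster_grid}} with nodata cells as \code{NA}.
#' @export
read_ascii_grid <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (length(lines) < 7L) stop("ASCII grid too short: ", path)
  hdr <- list()
  for (i in 1:6) {
    kv <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(kv) != 2L) stop("malformed header line ", i, " in ", path)
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
            "nodata_value")
  if (!all(need %in% names(hdr)))
    stop("ASCII grid header missing fields in ", path)
  vals <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  if (length(vals) != nc * nr)
    stop("ASCII grid value count ", length(vals), " != ncols*nrows = ",
         nc * nr, " in ", path)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == hdr$nodata_value] <- NA_real_
  raster_grid(m, hdr$xllcorner, hdr$yllcorner, hdr$cellsize, hdr$nodata_value)
}

#' Write an ESRI ASCII grid
#'
#' Values are written with \code{format(..., digits = 17)} so that
#' \code{read_ascii_grid(write_ascii_grid(r))} round-trips to full double
#' precision.
#'
#' @param r an \code{\link{raster_grid}}.
#' @param path output file.
#' @export
write_ascii_grid <- function(r, path) {
  stopifnot(inherits(r, "asc_raster"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(paste("ncols", r$ncols),
               paste("nrows", r$nrows),
               paste("xllcorner", format(r$xllcorner, digits = 17)),
               paste("yllcorner", format(r$yllcorner, digits = 17)),
               paste("cellsize", format(r$cellsize, digits = 17)),
               paste("NODATA_value", format(r$nodata_value, digits = 17))),
             con)
  m <- r$values
  m[is.na(m)] <- r$nodata_value
  for (i in seq_len(r$nrows))
    writeLines(paste(format(m[i, ], digits = 17, trim = TRUE),
                     collapse = " "), con)
  invisible(path)
}

#' Do two rasters share one header?
#' @param a,b \code{asc_raster} objects.
#' @return logical.
#' @export
same_header <- function(a, b) {
  isTRUE(all.equal(a[c("ncols", "nrows", "xllcorner", "yllcorner",
                       "cellsize")],
                   b[c("ncols", "nrows", "xllcorner", "yllcorner",
                       "cellsize")]))
}

#' Bundle rasters that share one header into a climate stack
#' @param ... named \code{asc_raster} layers, or a single named list.
#' @return object of class \code{climate_stack} (named list of rasters).
#' @export
climate_stack <- function(...) {
  layers <- list(...)
  if (length(layers) == 1L && is.list(layers[[1]]) &&
      !inherits(layers[[1]], "asc_raster"))
    layers <- layers[[1]]
  if (is.null(names(layers)) || any(!nzchar(names(layers))))
    stop("climate_stack layers must be named")
  for (l in layers) stopifnot(inherits(l, "asc_raster"))
  for (l in layers[-1])
    if (!same_header(layers[[1]], l))
      stop("climate_stack layers do not share one header")
  structure(layers, class = "climate_stack")
}

#' Mean of a raster's non-nodata cells
#' @param r an \code{asc_raster}.
#' @return numeric scalar.
#' @export
raster_mean <- function(r) mean(r$values, na.rm = TRUE)
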
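#' Read a reconstructed genome structure
#'
#' Parses a Dip-C style `.3dg` particle table: one particle per line,
#' whitespace-separated `chrom(hap) pos x y z` (diploid) or
#' `chrom pos x y z` (haploid/unphased). Each particle is one genomic bin
#' of the reconstruction with its 3D coordinate in the reconstruction's
#' arbitrary length unit.
#'
#' @param path Path to the text file.
#' @param dialect `"3dg"` (default) or `"tsv"`; both accept the same
#'   whitespace-separated grammar, `"tsv"` additionally skips a header line
#'   if the second field is not numeric.
#' @param resolution Bin size in bp. If `NULL` (default) it is inferred as
#'   the minimum positive spacing between consecutive positions within a
#'   (chrom, haplotype) group.
#' @param cell_id Identifier stored on the returned object; defaults to the
#'   file name without extension.
#'
#' @return A `genome_structure`: a data.frame with columns `chrom`, `hap`
#'   (`"pat"`, `"mat"` or `"none"`), `pos`, `x`, `y`, `z`, and attributes
#'   `resolution` and `cell_id`.
#'
#' @details At least 8 particles are required (the cube-length heuristic
#'   needs a 7th nearest neighbour). Duplicate `(chrom, hap, pos)` triples
#'   and malformed coordinates are errors reporting the offending line.
#'   Haplotype suffixes other than `(pat)`/`(mat)` are rejected.
#'
#' @examples
#' f <- tempfile(fileext = ".3dg")
#' writeLines(c("1(pat) 0 0 0 0", "1(pat) 20000 1 0 0", "1(pat) 40000 0 1 0",
#'              "1(mat) 0 0 0 1", "1(mat) 20000 1 1 0", "1(mat) 40000 1 0 1",
#'              "2(pat) 0 0 1 1", "2(pat) 20000 1 1 1"), f)
#' gs <- read_structure(f)
#' attr(gs, "resolution")
#' @export
read_structure <- function(path, dialect = c("3dg", "tsv"),
                           resolution = NULL, cell_id = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  lineno <- which(keep)
  lines <- lines[keep]
  if (dialect == "tsv" && length(lines)) {
    fields1 <- strsplit(trimws(lines[1]), "[ \t]+")[[1]]
    if (length(fields1) >= 2 && is.na(suppressWarnings(as.numeric(fields1[2])))) {
      lines <- lines[-1]
      lineno <- lineno[-1]
    }
  }
  if (!length(lines)) stop("too few particles: 0 (need >= 8)")
  parts <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(parts)
  if (any(nf != 5L)) {
    bad <- which(nf != 5L)[1]
    stop("parse error at line ", lineno[bad], ": expected 5 fields, got ", nf[bad])
  }
  m <- matrix(unlist(parts), ncol = 5, byrow = TRUE)
  chrom_raw <- m[, 1]
  hap <- rep("none", nrow(m))
  has_suffix <- grepl("\\(", chrom_raw)
  ok <- grepl("^[^()]+\\((pat|mat)\\)$", chrom_raw)
  if (any(has_suffix & !ok)) {
    bad <- which(has_suffix & !ok)[1]
    stop("parse error at line ", lineno[bad],
         ": unrecognized haplotype suffix in '", chrom_raw[bad], "'")
  }
  hap[has_suffix] <- sub("^.*\\((pat|mat)\\)$", "\\1", chrom_raw[has_suffix])
  chrom <- sub("\\((pat|mat)\\)$", "", chrom_raw)
  num <- suppressWarnings(apply(m[, 2:5, drop = FALSE], 2, as.numeric))
  if (nrow(m) == 1) num <- matrix(num, nrow = 1)
  if (anyNA(num) || any(!is.finite(num))) {
    bad <- which(rowSums(is.na(num) | !is.finite(num)) > 0)[1]
    stop("parse error at line ", lineno[bad], ": malformed coordinate")
  }
  pos <- num[, 1]
  if (any(pos < 0)) {
    bad <- which(pos < 0)[1]
    stop("parse error at line ", lineno[bad], ": negative genomic position")
  }
  df <- data.frame(chrom = chrom, hap = hap, pos = pos,
                   x = num[, 2], y = num[, 3], z = num[, 4],
                   stringsAsFactors = FALSE)
  if (is.null(cell_id)) cell_id <- sub("\\.[^.]*$", "", basename(path))
  genome_structure(df, resolution = resolution, cell_id = cell_id)
}

#' Construct a genome_structure from a particle data.frame
#'
#' @param particles data.frame with columns `chrom`, `hap`, `pos`, `x`,
#'   `y`, `z`.
#' @param resolution bp per particle; inferred from position spacing if
#'   `NULL`.
#' @param cell_id identifier string.
#' @return A `genome_structure` object.
#' @export
genome_structure <- function(particles, resolution = NULL, cell_id = "cell") {
  req <- c("chrom", "hap", "pos", "x", "y", "z")
  if (!all(req %in% names(particles))) {
    stop("particles must have columns: ", paste(req, collapse = ", "))
  }
  particles <- as.data.frame(particles)[, req]
  n <- nrow(particles)
  if (n < 8) stop("too few particles: ", n, " (need >= 8)")
  key <- paste(particles$chrom, particles$hap, particles$pos)
  if (anyDuplicated(key)) {
    stop("duplicate (chrom, hap, pos) triple: ", key[anyDuplicated(key)])
  }
  if (any(!is.finite(as.matrix(particles[, c("x", "y", "z")])))) {
    stop("non-finite coordinates")
  }
  if (is.null(resolution)) resolution <- infer_resolution(particles)
  if (any(particles$pos %% resolution != 0)) {
    stop("positions are not multiples of the resolution (", resolution, ")")
  }
  structure(particles, class = c("genome_structure", "data.frame"),
            resolution = resolution, cell_id = cell_id)
}

infer_resolution <- function(particles) {
  spacing <- unlist(lapply(
    split(particles$pos, paste(particles$chrom, particles$hap)),
    function(p) diff(sort(unique(p)))), use.names = FALSE)
  spacing <- spacing[spacing > 0]
  if (!length(spacing)) stop("cannot infer resolution: no position spacing")
  min(spacing)
}

#' @export
print.genome_structure <- function(x, ...) {
  cat("genome_structure '", attr(x, "cell_id"), "': ", nrow(x),
      " particles, resolution ", attr(x, "resolution"), " bp\n", sep = "")
  invisible(x)
}

#' Write a genome structure as a `.3dg` table
#'
#' @param structure A `genome_structure`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(structure, path) {
  chrom <- ifelse(structure$hap == "none", structure$chrom,
                  sprintf("%s(%s)", structure$chrom, structure$hap))
  lines <- sprintf("%s\t%s\t%s\t%s\t%s", chrom,
                   format(structure$pos, scientific = FALSE, trim = TRUE),
                   format(structure$x, digits = 15, trim = TRUE),
                   format(structure$y, digits = 15, trim = TRUE),
                   format(structure$z, digits = 15, trim = TRUE))
  writeLines(lines, path)
  invisible(path)
}

#' Write a per-cell density/DisTP table
#'
#' Serializes a `cell_d2` table (the per-particle output of [score_cell()])
#' as TSV with header `chrom hap start end density distp`. Coordinates are
#' 0-based half-open; `end = start + resolution`.
#'
#' @param table A `cell_d2` table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cell_d2 <- function(table, path) {
  if (!inherits(table, "cell_d2")) stop("not a cell_d2 table")
  if (nrow(table) == 0) stop("empty cell_d2 table")
  res <- attr(table, "resolution")
  out <- data.frame(chrom = table$chrom, hap = table$hap,
                    start = table$start, end = table$start + res,
                    density = table$density, distp = table$distp)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# cell_id=", attr(table, "cell_id"),
                    " resolution=", res), con)
  write.table(format(out, digits = 17, scientific = FALSE, trim = TRUE),
              con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-cell density/DisTP table written by [write_cell_d2()]
#'
#' @param path Input path.
#' @return A `cell_d2` table.
#' @export
read_cell_d2 <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1)
  cell_id <- "cell"; res <- NULL
  if (startsWith(first, "#")) {
    cell_id <- sub(".*cell_id=([^ ]+).*", "\\1", first)
    res <- as.numeric(sub(".*resolution=([0-9.eE+]+).*", "\\1", first))
  }
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE,
                   colClasses = c("character", "character", "numeric",
                                  "numeric", "numeric", "numeric"))
  if (is.null(res) || !is.finite(res)) res <- df$end[1] - df$start[1]
  cell_d2(df[, c("chrom", "hap", "start", "density", "distp")],
          resolution = res, cell_id = cell_id)
}

cell_d2 <- function(df, resolution, cell_id, n_dropped = 0L) {
  structure(as.data.frame(df), class = c("cell_d2", "data.frame"),
            resolution = resolution, cell_id = cell_id, n_dropped = n_dropped)
}

#' @export
print.cell_d2 <- function(x, ...) {
  cat("cell_d2 '", attr(x, "cell_id"), "': ", nrow(x), " segments (",
      attr(x, "n_dropped"), " outlier particles dropped), resolution ",
      attr(x, "resolution"), " bp\n", sep = "")
  invisible(x)
}

#' Segment identifiers for a table of genomic bins
#'
#' The haplotype-resolved segment id is `chrom:hap:bin_index` with
#' `bin_index = start / resolution`; it is the unit "g" of the occupancy
#' matrix.
#'
#' @param df data.frame with `chrom`, `hap` and `start` (or `pos`).
#' @param resolution bp per bin.
#' @return Character vector of segment ids.
#' @export
segment_ids <- function(df, resolution) {
  start <- if ("start" %in% names(df)) df$start else df$pos
  paste(df$chrom, df$hap, start %/% resolution, sep = ":")
}
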
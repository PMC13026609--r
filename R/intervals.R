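# Genomic intervals (BED convention: 0-based half-open) and genetic maps.

#' Load mask intervals from a BED3 file
#'
#' Reads a 3-column BED file (chrom, start, end; 0-based half-open), sorts
#' the intervals and merges overlapping or bookended intervals within each
#' chromosome.
#'
#' @param path BED path.
#' @return Data frame `chrom, start, end`, sorted, non-overlapping; empty
#'   data frame for an empty file.
#' @export
load_intervals_bed <- function(path) {
  if (file.size(path) == 0)
    return(data.frame(chrom = integer(), start = numeric(), end = numeric()))
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)[, 1:3]
  names(df) <- c("chrom", "start", "end")
  df$chrom <- as.integer(sub("^chr", "", as.character(df$chrom)))
  bad <- which(df$start >= df$end)
  if (length(bad))
    stop_input("BED row %d: start %g >= end %g", bad[1], df$start[bad[1]], df$end[bad[1]])
  merge_intervals(df)
}

# Sort and merge (union) 0-based half-open intervals per chromosome.
merge_intervals <- function(df) {
  if (!nrow(df)) return(df)
  out <- lapply(sort(unique(df$chrom)), function(ci) {
    sub <- df[df$chrom == ci, , drop = FALSE]
    ir <- IRanges::reduce(IRanges::IRanges(start = sub$start + 1, end = sub$end))
    data.frame(chrom = ci, start = IRanges::start(ir) - 1, end = IRanges::end(ir))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Load a genetic map from TSV
#'
#' Reads a genetic map with header columns `chrom, pos, cM`: per-chromosome
#' anchor points with non-decreasing genetic position. Physical-to-genetic
#' interpolation between anchors is linear.
#'
#' @param path Map TSV path.
#' @return A `genetic_map`: list of per-chromosome data frames with columns
#'   `pos` (bp) and `cM`.
#' @export
load_genetic_map <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "pos", "cM") %in% names(df)))
  make_genetic_map(df)
}

make_genetic_map <- function(df) {
  df$chrom <- as.integer(df$chrom)
  chroms <- sort(unique(df$chrom))
  map <- lapply(chroms, function(ci) {
    sub <- df[df$chrom == ci, c("pos", "cM")]
    sub <- sub[order(sub$pos), ]
    if (any(diff(sub$cM) < 0))
      stop_input("genetic map chromosome %d: cM must be non-decreasing in pos", ci)
    if (nrow(sub) < 2)
      stop_input("genetic map chromosome %d: need at least two anchor points", ci)
    rownames(sub) <- NULL
    sub
  })
  names(map) <- chroms
  structure(map, class = "genetic_map")
}

#' Uniform genetic map over a panel
#'
#' Builds the default genetic map: a constant 1 cM/Mbp over each chromosome
#' covered by the manifest (a good genome-wide average for human autosomes),
#' extending from position 1 to the GRCh38 chromosome end so that crossovers
#' can fall outside panel coverage. Totals ~2,875 cM over 22 autosomes.
#'
#' @param manifest A `panel_manifest` (determines which chromosomes to cover).
#' @param cm_per_mbp Map density, centimorgans per megabase (default 1).
#' @return A `genetic_map`.
#' @export
uniform_genetic_map <- function(manifest, cm_per_mbp = 1) {
  lens <- grch38_autosome_lengths()
  chroms <- sort(unique(manifest$chrom))
  df <- do.call(rbind, lapply(chroms, function(ci) {
    end_bp <- max(round(lens[[as.character(ci)]] * 1e6), max(manifest$pos[manifest$chrom == ci]))
    data.frame(chrom = ci, pos = c(1, end_bp),
               cM = c(0, (end_bp - 1) / 1e6 * cm_per_mbp))
  }))
  make_genetic_map(df)
}

#' Write a genetic map to TSV
#' @param map A `genetic_map`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genetic_map <- function(map, path) {
  df <- do.call(rbind, lapply(names(map), function(ci)
    data.frame(chrom = as.integer(ci), pos = map[[ci]]$pos, cM = map[[ci]]$cM)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

map_chroms <- function(map) as.integer(names(map))

map_require_chrom <- function(map, chrom) {
  m <- map[[as.character(chrom)]]
  if (is.null(m))
    stop_input("genetic map does not cover chromosome %s", chrom)
  m
}

# bp -> cM (linear interpolation, clamped to the anchor range)
map_cm_at <- function(map, chrom, pos) {
  m <- map_require_chrom(map, chrom)
  stats::approx(m$pos, m$cM, xout = pos, rule = 2)$y
}

# cM -> bp (inverse interpolation)
map_pos_at <- function(map, chrom, cm) {
  m <- map_require_chrom(map, chrom)
  stats::approx(m$cM, m$pos, xout = cm, rule = 2, ties = "ordered")$y
}

map_length_cm <- function(map, chrom) {
  m <- map_require_chrom(map, chrom)
  max(m$cM) - min(m$cM)
}
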
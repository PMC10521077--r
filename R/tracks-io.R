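#' Binned genomic signal track
#'
#' The basic container of the package: one chromosome's signal in fixed-width
#' bins. Coordinates are 0-based half-open throughout (the native bedGraph
#' convention), so bin \code{i} (1-based index) covers
#' \code{[(i-1)*bin_size, i*bin_size)} and has midpoint \code{(i-0.5)*bin_size}.
#' Masked bins (e.g. bins clipped away by [clip_track()]) are stored as
#' \code{NA} -- never as zero -- so that sums, percentiles, peak calls and fits
#' exclude them.
#'
#' @param values numeric vector, one value per bin; \code{NA} marks a masked
#'   bin. For role \code{"raw_count"} values must be non-negative integers.
#' @param chrom chromosome name.
#' @param bin_size bin width in bp.
#' @param role one of \code{"raw_count"}, \code{"rpm"}, \code{"signal"}.
#' @param chrom_length declared chromosome length in bp; defaults to
#'   \code{length(values) * bin_size}. The last bin may be partial.
#'
#' @return an object of class \code{binned_track}.
#' @export
binned_track <- function(values, chrom, bin_size,
                         role = c("raw_count", "rpm", "signal"),
                         chrom_length = NULL) {
  role <- match.arg(role)
  stopifnot(is.numeric(values), length(chrom) == 1L, bin_size > 0)
  values <- as.numeric(values)
  if (role == "raw_count") {
    ok <- is.na(values) | (values >= 0 & values == round(values))
    if (!all(ok)) stop("raw_count values must be non-negative integers")
  }
  if (role == "rpm" && any(values < 0, na.rm = TRUE))
    stop("rpm values must be non-negative")
  if (is.null(chrom_length)) chrom_length <- length(values) * bin_size
  if (chrom_length > length(values) * bin_size ||
      chrom_length <= (length(values) - 1L) * bin_size)
    stop("chrom_length inconsistent with number of bins")
  structure(
    list(chrom = as.character(chrom), bin_size = as.numeric(bin_size),
         start_offset = 0, values = values, role = role,
         chrom_length = as.numeric(chrom_length)),
    class = "binned_track")
}

#' @export
print.binned_track <- function(x, ...) {
  cat(sprintf("<binned_track> %s: %d x %g bp bins (role: %s, %d masked)\n",
              x$chrom, length(x$values), x$bin_size, x$role,
              sum(is.na(x$values))))
  invisible(x)
}

#' @export
length.binned_track <- function(x) length(x$values)

#' Bin midpoints of a track, in bp
#' @param track a [binned_track()].
#' @return numeric vector of midpoints.
#' @export
track_midpoints <- function(track) {
  (seq_along(track$values) - 0.5) * track$bin_size
}

#' Sum of a track's unmasked values
#' @param track a [binned_track()].
#' @export
track_sum <- function(track) sum(track$values, na.rm = TRUE)

## apply f over a single track or a named list of tracks
map_tracks <- function(x, f, ...) {
  if (inherits(x, "binned_track")) return(f(x, ...))
  stopifnot(is.list(x))
  out <- lapply(x, f, ...)
  names(out) <- names(x)
  out
}

## gather unmasked values across a track or track list
gather_values <- function(x) {
  if (inherits(x, "binned_track")) return(x$values)
  unlist(lapply(x, function(t) t$values), use.names = FALSE)
}

check_same_grid <- function(a, b) {
  if (a$chrom != b$chrom || a$bin_size != b$bin_size ||
      length(a$values) != length(b$values))
    stop("tracks are not on the same bin grid (", a$chrom, " vs ", b$chrom, ")")
  invisible(TRUE)
}

#' Genomic region set
#'
#' A sorted, merged set of half-open intervals used for clipping and peak
#' region filters.
#'
#' @param chrom,start,end equal-length vectors of intervals (0-based
#'   half-open, \code{start < end}).
#' @return a \code{region_set}: a data.frame with columns
#'   \code{chrom,start,end}, sorted and overlap-merged per chromosome.
#' @export
region_set <- function(chrom = character(), start = numeric(),
                       end = numeric()) {
  stopifnot(length(chrom) == length(start), length(start) == length(end))
  df <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                   end = as.numeric(end), stringsAsFactors = FALSE)
  if (nrow(df) && any(df$start >= df$end)) stop("regions require start < end")
  out <- do.call(rbind, lapply(split(df, df$chrom), function(d) {
    d <- d[order(d$start), , drop = FALSE]
    m <- merge_intervals(cbind(d$start, d$end))
    data.frame(chrom = d$chrom[1], start = m[, 1], end = m[, 2],
               stringsAsFactors = FALSE)
  }))
  if (is.null(out)) out <- df
  rownames(out) <- NULL
  class(out) <- c("region_set", "data.frame")
  out
}

#' Which bins of a track lie inside a region set?
#'
#' Membership is decided by the bin midpoint.
#'
#' @param track a [binned_track()].
#' @param regions a [region_set()] (rows on other chromosomes are ignored).
#' @return logical vector, one element per bin.
#' @export
bins_in_regions <- function(track, regions) {
  mid <- track_midpoints(track)
  inside <- rep(FALSE, length(mid))
  r <- regions[regions$chrom == track$chrom, , drop = FALSE]
  for (k in seq_len(nrow(r)))
    inside <- inside | (mid >= r$start[k] & mid < r$end[k])
  inside
}

#' Mask a track outside a region set
#'
#' Bins whose midpoint lies outside \code{regions} are set to \code{NA} and
#' excluded from all downstream sums, peak calls and percentiles.
#'
#' @inheritParams bins_in_regions
#' @return the clipped [binned_track()].
#' @export
clip_track <- function(track, regions) {
  v <- track$values
  v[!bins_in_regions(track, regions)] <- NA_real_
  track$values <- v
  track
}

#' Read a 4-column bedGraph file into binned tracks
#'
#' Every interval must align to the declared bin grid (start a multiple of
#' \code{bin_size}, span one bin -- a shorter final interval is accepted as a
#' partial last bin). Bins absent from the file are zero-filled: in a
#' genome-wide count track absence means zero coverage, not missing data.
#'
#' @param path bedGraph file (4 columns: chrom, start, end, value; track/
#'   browser/comment lines are skipped).
#' @param bin_size declared bin width in bp.
#' @param role stored role of the resulting tracks, see [binned_track()].
#' @param chrom_lengths optional named vector of chromosome lengths; when
#'   omitted each chromosome runs to the end of its last listed interval.
#' @return named list of [binned_track()], one per chromosome.
#' @export
read_bedgraph <- function(path, bin_size, role = "signal",
                          chrom_lengths = NULL) {
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  lines <- lines[keep]
  if (!length(lines)) return(list())
  fields <- strsplit(lines, "[ \t]+")
  bad <- which(lengths(fields) < 4L)
  if (length(bad))
    stop("bedGraph format error at line ", bad[1], ": fewer than 4 fields")
  chrom <- vapply(fields, `[`, "", 1L)
  start <- as.numeric(vapply(fields, `[`, "", 2L))
  end <- as.numeric(vapply(fields, `[`, "", 3L))
  val <- as.numeric(vapply(fields, `[`, "", 4L))
  if (anyNA(start) || anyNA(end) || anyNA(val))
    stop("bedGraph format error: non-numeric coordinates or value")
  mis <- which(start %% bin_size != 0 | end <= start |
                 end - start > bin_size)
  if (length(mis))
    stop("bedGraph interval not aligned to the ", bin_size,
         "-bp bin grid at line ", mis[1])
  out <- list()
  for (ch in unique(chrom)) {
    i <- chrom == ch
    s <- start[i]; e <- end[i]; v <- val[i]
    len <- if (!is.null(chrom_lengths) && ch %in% names(chrom_lengths))
      chrom_lengths[[ch]] else max(e)
    part <- which(e - s < bin_size & e != len)
    if (length(part))
      stop("short bedGraph interval not at chromosome end (", ch, ":",
           s[part[1]], ")")
    n <- as.integer(ceiling(len / bin_size))
    idx <- s %/% bin_size + 1L
    if (anyDuplicated(idx))
      stop("overlapping bedGraph intervals on ", ch)
    values <- numeric(n)
    values[idx] <- v
    out[[ch]] <- binned_track(values, ch, bin_size, role = role,
                              chrom_length = len)
  }
  out
}

#' Write binned tracks as bedGraph
#'
#' Masked bins are omitted; signed (negative) values are written verbatim.
#'
#' @param tracks a [binned_track()] or named list of them (shared
#'   \code{bin_size}).
#' @param path output file.
#' @param suppress_zero drop zero-valued bins from the output body.
#' @return \code{path}, invisibly.
#' @export
write_bedgraph <- function(tracks, path, suppress_zero = FALSE) {
  if (inherits(tracks, "binned_track")) tracks <- list(tracks)
  bs <- unique(vapply(tracks, function(t) t$bin_size, 0))
  if (length(bs) > 1) stop("tracks must share bin_size")
  con <- file(path, "w")
  on.exit(close(con))
  for (t in tracks) {
    v <- t$values
    keep <- !is.na(v)
    if (suppress_zero) keep <- keep & v != 0
    i <- which(keep)
    if (!length(i)) next
    s <- (i - 1L) * t$bin_size
    e <- pmin(i * t$bin_size, t$chrom_length)
    writeLines(sprintf("%s\t%s\t%s\t%s", t$chrom,
                       format(s, scientific = FALSE, trim = TRUE),
                       format(e, scientific = FALSE, trim = TRUE),
                       format(v[i], scientific = FALSE, trim = TRUE)), con)
  }
  invisible(path)
}

#' Bin read intervals into count tracks
#'
#' Each read interval increments by one the bin containing its fragment
#' midpoint, so a read is never split across bins.
#'
#' @param reads data.frame with columns \code{chrom,start,end} (0-based
#'   half-open).
#' @param bin_size bin width in bp.
#' @param chrom_lengths named vector of chromosome lengths in bp; reads whose
#'   midpoint falls outside the declared length are rejected with a warning.
#' @return named list of raw-count [binned_track()].
#' @export
bin_intervals <- function(reads, bin_size, chrom_lengths) {
  stopifnot(all(c("chrom", "start", "end") %in% names(reads)))
  out <- list()
  n_rejected <- 0L
  for (ch in names(chrom_lengths)) {
    len <- chrom_lengths[[ch]]
    n <- as.integer(ceiling(len / bin_size))
    r <- reads[reads$chrom == ch, , drop = FALSE]
    mid <- (r$start + r$end) / 2
    ok <- mid >= 0 & mid < len
    n_rejected <- n_rejected + sum(!ok)
    idx <- floor(mid[ok] / bin_size) + 1L
    counts <- tabulate(idx, nbins = n)
    out[[ch]] <- binned_track(counts, ch, bin_size, role = "raw_count",
                              chrom_length = len)
  }
  extra <- sum(!reads$chrom %in% names(chrom_lengths))
  n_rejected <- n_rejected + extra
  if (n_rejected > 0L)
    warning(n_rejected, " read(s) outside declared chromosomes rejected")
  out
}

#' Load replication-timing domains from a tab-delimited RT track
#'
#' Consecutive runs of bins with RT value > 0 are merged into \code{early}
#' intervals and runs with RT < 0 into \code{late} intervals; bins with RT
#' exactly 0 are assigned to neither label and leave a gap.
#'
#' @param path tab-delimited text file with chromosome, start, end and RT
#'   value columns (no header by default).
#' @param columns named integer vector mapping \code{chrom,start,end,rt} to
#'   column positions, for files with extra or reordered columns.
#' @param header does the file carry a header line?
#' @return a \code{timing_domains} object: data.frame with columns
#'   \code{chrom,start,end,label,domain_id} plus a \code{source} attribute.
#' @export
load_timing_domains <- function(path,
                                columns = c(chrom = 1, start = 2, end = 3,
                                            rt = 4),
                                header = FALSE) {
  df <- utils::read.table(path, header = header, sep = "\t",
                          stringsAsFactors = FALSE)
  rt <- suppressWarnings(as.numeric(df[[columns[["rt"]]]]))
  if (anyNA(rt)) stop("non-numeric RT value at row ", which(is.na(rt))[1])
  timing_domains(data.frame(
    chrom = as.character(df[[columns[["chrom"]]]]),
    start = as.numeric(df[[columns[["start"]]]]),
    end = as.numeric(df[[columns[["end"]]]]),
    rt = rt, stringsAsFactors = FALSE), source = path)
}

#' Build a timing-domain set from per-bin RT values or explicit intervals
#'
#' @param df data.frame with columns \code{chrom,start,end} and either
#'   \code{rt} (sign decides early/late) or \code{label}
#'   (\code{"early"}/\code{"late"}).
#' @param source provenance string stored on the object.
#' @return a \code{timing_domains} data.frame (sorted, runs merged, with
#'   unique \code{domain_id}s).
#' @export
timing_domains <- function(df, source = "constructed") {
  if (!is.null(df$rt)) {
    lab <- ifelse(df$rt > 0, "early", ifelse(df$rt < 0, "late", NA))
    df$label <- lab
    df <- df[!is.na(lab), , drop = FALSE]
  }
  stopifnot(all(c("chrom", "start", "end", "label") %in% names(df)))
  if (any(df$start >= df$end)) stop("domain intervals require start < end")
  pieces <- lapply(split(df, df$chrom), function(d) {
    d <- d[order(d$start), , drop = FALSE]
    # merge abutting/overlapping runs of the same label
    brk <- c(TRUE, d$label[-1] != d$label[-nrow(d)] |
               d$start[-1] > d$end[-nrow(d)])
    run <- cumsum(brk)
    data.frame(chrom = d$chrom[1],
               start = tapply(d$start, run, min),
               end = tapply(d$end, run, max),
               label = tapply(d$label, run, `[`, 1L),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  for (lab in c("early", "late")) {
    d <- out[out$label == lab, , drop = FALSE]
    for (ch in unique(d$chrom)) {
      dd <- d[d$chrom == ch, , drop = FALSE]
      if (nrow(dd) > 1 && any(dd$start[-1] < dd$end[-nrow(dd)]))
        stop("overlapping ", lab, " domains on ", ch)
    }
  }
  out$domain_id <- sprintf("%s_%s_%d", out$label, out$chrom,
                           stats::ave(seq_len(nrow(out)),
                                      paste(out$chrom, out$label),
                                      FUN = seq_along))
  attr(out, "source") <- source
  class(out) <- c("timing_domains", "data.frame")
  out
}

#' Extract one label of a timing-domain set as a region set
#' @param domains a [timing_domains()] object.
#' @param label \code{"early"} or \code{"late"}.
#' @return a [region_set()].
#' @export
domain_regions <- function(domains, label = c("early", "late")) {
  label <- match.arg(label)
  d <- domains[domains$label == label, , drop = FALSE]
  region_set(d$chrom, d$start, d$end)
}

#' Which timing domain contains a position?
#' @param domains a [timing_domains()] object.
#' @param chrom,position vectors of genomic positions.
#' @return character vector of \code{domain_id} (\code{NA} if unlabelled).
#' @export
domain_at <- function(domains, chrom, position) {
  vapply(seq_along(position), function(i) {
    hit <- domains$chrom == chrom[i] & domains$start <= position[i] &
      domains$end > position[i]
    if (any(hit)) domains$domain_id[which(hit)[1]] else NA_character_
  }, character(1))
}
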
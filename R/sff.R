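SFF_MAGIC <- as.raw(c(0x2e, 0x73, 0x66, 0x66)) # ".sff"
SFF_VERSION <- as.raw(c(0x00, 0x00, 0x00, 0x01))

#' SFF file header
#'
#' Describes one 454 run: the cyclic order of nucleotide flows and the key
#' sequence. The number of flows per read equals `nchar(flow_order)`.
#'
#' @param flow_order String over A/C/G/T giving the base flowed at each flow.
#' @param key_sequence Key sequence (default `"TCAG"`); metadata only, reads
#'   handled by this package are stored key-stripped.
#' @return A list of class `sff_header`.
#' @examples
#' sff_header(strrep("TACG", 5))
#' @export
sff_header <- function(flow_order, key_sequence = "TCAG") {
  stopifnot(is.character(flow_order), length(flow_order) == 1,
            nchar(flow_order) > 0)
  if (grepl("[^ACGT]", flow_order))
    stop("flow_order must contain only A, C, G, T")
  structure(
    list(flow_order = flow_order,
         key_sequence = key_sequence,
         number_of_flows = nchar(flow_order)),
    class = "sff_header"
  )
}

#' @export
print.sff_header <- function(x, ...) {
  cat("<sff_header> ", x$number_of_flows, " flows, key ", x$key_sequence,
      ", order ", substr(x$flow_order, 1, 12), "...\n", sep = "")
  invisible(x)
}

#' Build a tibble of flow reads
#'
#' One row per read. `flow_values` are integer hundredths of the flow signal
#' (a stored value of 612 means signal 6.12); `flow_index` holds, for each
#' called base, the 1-based flow at which it was called (absolute values,
#' non-decreasing). Clip points are 1-based; 0 means absent.
#'
#' @param name Character vector of read names.
#' @param flow_values List of integer vectors (one per read).
#' @param flow_index List of integer vectors, one entry per called base.
#' @param bases Character vector of called sequences.
#' @param quality List of integer Phred scores, one per base.
#' @param clip_qual_left,clip_qual_right,clip_adapter_left,clip_adapter_right
#'   Integer clip points (recycled).
#' @return A tibble with class `flow_reads`.
#' @export
flow_reads <- function(name, flow_values, flow_index, bases, quality,
                       clip_qual_left = 0L, clip_qual_right = 0L,
                       clip_adapter_left = 0L, clip_adapter_right = 0L) {
  out <- tibble::tibble(
    name = as.character(name),
    flow_values = as.list(flow_values),
    flow_index = as.list(flow_index),
    bases = as.character(bases),
    quality = as.list(quality),
    clip_qual_left = as.integer(clip_qual_left),
    clip_qual_right = as.integer(clip_qual_right),
    clip_adapter_left = as.integer(clip_adapter_left),
    clip_adapter_right = as.integer(clip_adapter_right)
  )
  class(out) <- c("flow_reads", class(out))
  out
}

#' Validate flow reads against a header
#'
#' Checks the structural invariants of a set of reads: per-base vectors have
#' one entry per called base, flow indices are non-decreasing and within the
#' flow count, and every called base matches the flow-order character of its
#' flow.
#'
#' @param reads A `flow_reads` tibble.
#' @param header An `sff_header`.
#' @return `reads`, invisibly; errors on the first violated invariant.
#' @export
validate_flow_reads <- function(reads, header) {
  flow_chars <- strsplit(header$flow_order, "")[[1]]
  nf <- header$number_of_flows
  for (i in seq_len(nrow(reads))) {
    nb <- nchar(reads$bases[[i]])
    fi <- reads$flow_index[[i]]
    if (length(fi) != nb || length(reads$quality[[i]]) != nb)
      stop("read ", i, " (", reads$name[[i]],
           "): bases, quality and flow_index lengths differ")
    if (length(reads$flow_values[[i]]) != nf)
      stop("read ", i, ": expected ", nf, " flow values, got ",
           length(reads$flow_values[[i]]))
    if (nb > 0) {
      if (any(diff(fi) < 0))
        stop("read ", i, ": flow_index_per_base decreases")
      if (any(fi < 1 | fi > nf))
        stop("read ", i, ": flow index outside [1, ", nf, "]")
      if (nb > 1 && any(diff(fi) > 255))
        stop("read ", i, ": flow index delta exceeds 255 (not encodable)")
      if (fi[1] > 255)
        stop("read ", i, ": first flow index exceeds 255 (not encodable)")
      b <- strsplit(reads$bases[[i]], "")[[1]]
      if (!all(b == flow_chars[fi]))
        stop("read ", i, ": called base disagrees with flow order at its flow")
      if (any(reads$flow_values[[i]] < 0))
        stop("read ", i, ": negative flow value")
    }
  }
  invisible(reads)
}

pad8 <- function(n) as.integer((8 - n %% 8) %% 8)

write_u16 <- function(con, x) writeBin(as.integer(x), con, size = 2,
                                       endian = "big")
write_u32 <- function(con, x) writeBin(as.integer(x), con, size = 4,
                                       endian = "big")

read_u16 <- function(con, n = 1) readBin(con, "integer", n = n, size = 2,
                                         signed = FALSE, endian = "big")
read_u32 <- function(con, n = 1) readBin(con, "integer", n = n, size = 4,
                                         endian = "big")
read_u8 <- function(con, n = 1) readBin(con, "integer", n = n, size = 1,
                                        signed = FALSE, endian = "big")

#' Write an SFF file
#'
#' Serializes a header and a set of flow reads to the public big-endian SFF
#' v1 layout (flowgram format code 1: one unsigned 16-bit value per flow, in
#' hundredths). Per-base flow indices are delta-encoded on disk; in memory
#' they are absolute. Records are padded to 8-byte boundaries. No read-index
#' block is written. Reads are validated before any byte is written.
#'
#' @param header An `sff_header`.
#' @param reads A `flow_reads` tibble (may have zero rows).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_sff()]
#' @export
write_sff <- function(header, reads, path) {
  stopifnot(inherits(header, "sff_header"))
  validate_flow_reads(reads, header)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(SFF_MAGIC, con)
  writeBin(SFF_VERSION, con)
  writeBin(raw(8), con)                       # index_offset = 0
  write_u32(con, 0L)                          # index_length = 0
  write_u32(con, nrow(reads))
  key_len <- nchar(header$key_sequence)
  hlen_raw <- 31L + header$number_of_flows + key_len
  hlen <- hlen_raw + pad8(hlen_raw)
  write_u16(con, hlen)
  write_u16(con, key_len)
  write_u16(con, header$number_of_flows)
  writeBin(as.raw(1L), con)                   # flowgram_format_code
  writeBin(charToRaw(header$flow_order), con)
  writeBin(charToRaw(header$key_sequence), con)
  writeBin(raw(pad8(hlen_raw)), con)
  for (i in seq_len(nrow(reads))) {
    nm <- reads$name[[i]]
    nb <- nchar(reads$bases[[i]])
    rhl_raw <- 16L + nchar(nm)
    rhl <- rhl_raw + pad8(rhl_raw)
    write_u16(con, rhl)
    write_u16(con, nchar(nm))
    write_u32(con, nb)
    write_u16(con, reads$clip_qual_left[[i]])
    write_u16(con, reads$clip_qual_right[[i]])
    write_u16(con, reads$clip_adapter_left[[i]])
    write_u16(con, reads$clip_adapter_right[[i]])
    writeBin(charToRaw(nm), con)
    writeBin(raw(pad8(rhl_raw)), con)
    write_u16(con, reads$flow_values[[i]])
    fi <- reads$flow_index[[i]]
    deltas <- if (nb > 0) diff(c(0L, fi)) else integer(0)
    writeBin(as.raw(deltas), con)
    if (nb > 0) writeBin(charToRaw(reads$bases[[i]]), con)
    writeBin(as.raw(reads$quality[[i]]), con)
    dlen_raw <- 2L * header$number_of_flows + 3L * nb
    writeBin(raw(pad8(dlen_raw)), con)
  }
  invisible(path)
}

#' Read an SFF file
#'
#' Parses the public big-endian SFF v1 layout. The optional read-index block
#' is skipped. On-disk delta-encoded per-base flow indices are converted to
#' absolute values.
#'
#' @param path Path to an SFF file.
#' @return A list of class `sff` with elements `header` (an [sff_header()])
#'   and `reads` (a [flow_reads()] tibble).
#' @seealso [write_sff()]
#' @export
read_sff <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 4)
  if (length(magic) < 4 || !identical(magic, SFF_MAGIC))
    stop("not an SFF file (bad magic at offset 0): ", path)
  version <- readBin(con, "raw", 4)
  if (!identical(version, SFF_VERSION))
    stop("unsupported SFF version at offset 4 in ", path)
  index_off_raw <- readBin(con, "raw", 8)
  index_offset <- sum(as.numeric(index_off_raw) * 256^(7:0))
  index_length <- read_u32(con)
  n_reads <- read_u32(con)
  hlen <- read_u16(con)
  key_len <- read_u16(con)
  n_flows <- read_u16(con)
  fmt <- read_u8(con)
  if (fmt != 1L)
    stop("unsupported flowgram format code ", fmt, " at offset 30")
  flow_order <- rawToChar(readBin(con, "raw", n_flows))
  key_sequence <- rawToChar(readBin(con, "raw", key_len))
  readBin(con, "raw", hlen - 31L - n_flows - key_len)
  header <- sff_header(flow_order, key_sequence)

  nm <- character(n_reads)
  fvs <- vector("list", n_reads)
  fis <- vector("list", n_reads)
  bss <- character(n_reads)
  qls <- vector("list", n_reads)
  clips <- matrix(0L, nrow = n_reads, ncol = 4)
  i <- 0L
  while (i < n_reads) {
    i <- i + 1L
    # skip an index block if it sits between records
    pos <- seek(con, where = NA)
    if (index_length > 0 && pos == index_offset)
      readBin(con, "raw", index_length + pad8(index_length))
    rhl <- read_u16(con)
    if (length(rhl) == 0) stop("truncated SFF: read record ", i, " missing")
    name_len <- read_u16(con)
    nb <- read_u32(con)
    cl <- read_u16(con, 4)
    nm[i] <- rawToChar(readBin(con, "raw", name_len))
    readBin(con, "raw", rhl - 16L - name_len)
    fv <- read_u16(con, n_flows)
    deltas <- read_u8(con, nb)
    b <- rawToChar(readBin(con, "raw", nb))
    q <- read_u8(con, nb)
    if (length(fv) < n_flows || length(q) < nb || nchar(b) < nb)
      stop("truncated SFF: read record ", i, " incomplete")
    readBin(con, "raw", pad8(2L * n_flows + 3L * nb))
    fvs[[i]] <- fv
    fis[[i]] <- cumsum(deltas)
    bss[i] <- b
    qls[[i]] <- q
    clips[i, ] <- cl
  }
  reads <- flow_reads(nm, fvs, fis, bss, qls,
                      clip_qual_left = clips[, 1], clip_qual_right = clips[, 2],
                      clip_adapter_left = clips[, 3],
                      clip_adapter_right = clips[, 4])
  validate_flow_reads(reads, header)
  structure(list(header = header, reads = reads), class = "sff")
}

#' @export
print.sff <- function(x, ...) {
  cat("<sff> ", nrow(x$reads), " reads, ", x$header$number_of_flows,
      " flows\n", sep = "")
  invisible(x)
}

#' Map a called base to its flow
#'
#' Returns the 1-based flow index at which base `base_index` (0-based, as in
#' the on-disk convention) of a read was called. All bases of one
#' homopolymer run map to the same flow.
#'
#' @param read One row of a [flow_reads()] tibble (or a list with
#'   `flow_index` and `bases`).
#' @param base_index 0-based base position.
#' @return Integer flow index (1-based).
#' @export
base_to_flow <- function(read, base_index) {
  fi <- if (is.list(read$flow_index) && !is.integer(read$flow_index))
    read$flow_index[[1]] else read$flow_index
  nb <- length(fi)
  if (any(base_index < 0 | base_index >= nb))
    stop("base_index out of range [0, ", nb - 1, "]")
  fi[base_index + 1L]
}

#' Apply quality clips to reads
#'
#' Restricts `bases`, `quality` and `flow_index` of each read to the
#' quality-clipped region (`clip_qual_left`..`clip_qual_right`, 1-based, 0
#' meaning unclipped). Flow values are left untouched, so [base_to_flow()]
#' remains valid on the clipped read. Downstream stages see clipped reads by
#' default.
#'
#' @param reads A [flow_reads()] tibble.
#' @return A `flow_reads` tibble with clipped per-base fields and clip points
#'   reset to 0.
#' @export
clip_reads <- function(reads) {
  for (i in seq_len(nrow(reads))) {
    nb <- nchar(reads$bases[[i]])
    from <- max(1L, reads$clip_qual_left[[i]], reads$clip_adapter_left[[i]])
    to <- nb
    for (r in c(reads$clip_qual_right[[i]], reads$clip_adapter_right[[i]]))
      if (r > 0) to <- min(to, r)
    if (from > 1L || to < nb) {
      idx <- seq.int(from, to)
      reads$bases[[i]] <- substr(reads$bases[[i]], from, to)
      reads$quality[[i]] <- reads$quality[[i]][idx]
      reads$flow_index[[i]] <- reads$flow_index[[i]][idx]
    }
    reads$clip_qual_left[[i]] <- 0L
    reads$clip_qual_right[[i]] <- 0L
    reads$clip_adapter_left[[i]] <- 0L
    reads$clip_adapter_right[[i]] <- 0L
  }
  reads
}
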
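# Minimal DICOM reader: single-frame, uncompressed, little-endian transfer
# syntaxes (implicit VR 1.2.840.10008.1.2 and explicit VR 1.2.840.10008.1.2.1).
# Parses only the tags required to recover calibrated pixel values: matrix
# size, bit depth, pixel representation, rescale slope/intercept, pixel data.
# Compressed/encapsulated transfer syntaxes and undefined-length sequences
# are rejected with a clear error.

.DICOM_LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")

#' Read a single-frame DICOM slice
#'
#' @param path DICOM file path.
#' @return list with `pixels` (integer matrix, stored values, row x col),
#'   `slope`, `intercept` (rescale to HU), `bits`, `signed`.
#' @export
read_dicom_slice <- function(path) {
  n <- file.size(path)
  if (is.na(n) || n < 140) stop("unreadable DICOM file: ", path)
  raw <- readBin(path, "raw", n)
  if (rawToChar(raw[129:132]) != "DICM")
    stop("not a DICOM file (missing DICM magic): ", path)
  u16 <- function(i) as.integer(raw[i]) + 256L * as.integer(raw[i + 1L])
  u32 <- function(i) as.numeric(raw[i]) + 256 * as.numeric(raw[i + 1L]) +
    65536 * as.numeric(raw[i + 2L]) + 16777216 * as.numeric(raw[i + 3L])
  str_of <- function(bytes) sub("[\\0 ]+$", "", rawToChar(bytes))
  pos <- 133L
  implicit <- FALSE
  meta_end <- NA_real_
  tags <- list()
  want <- c("0002,0010", "0028,0010", "0028,0011", "0028,0100", "0028,0103",
            "0028,1052", "0028,1053", "7fe0,0010")
  while (pos + 7 <= n) {
    group <- u16(pos); elem <- u16(pos + 2L)
    in_meta <- group == 2L
    if (!in_meta && !is.na(meta_end) && pos <= meta_end) in_meta <- TRUE
    expl <- in_meta || !implicit
    if (expl) {
      vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
      if (vr %in% .DICOM_LONG_VRS) { len <- u32(pos + 8L); hdr <- 12L }
      else { len <- u16(pos + 6L); hdr <- 8L }
    } else { len <- u32(pos + 4L); hdr <- 8L }
    if (len == 4294967295)
      stop("undefined-length DICOM elements are not supported")
    key <- sprintf("%04x,%04x", group, elem)
    data_start <- pos + hdr
    if (key %in% want && len > 0)
      tags[[key]] <- raw[data_start:(data_start + len - 1L)]
    if (key == "0002,0010") {
      ts <- str_of(tags[[key]])
      if (ts == "1.2.840.10008.1.2") implicit <- TRUE
      else if (ts != "1.2.840.10008.1.2.1")
        stop("unsupported DICOM transfer syntax: ", ts,
             " (only uncompressed little-endian is handled)")
    }
    if (key == "0002,0000") meta_end <- data_start + len + u32(data_start) - 1
    pos <- as.integer(data_start + len)
  }
  need <- c("0028,0010", "0028,0011", "7fe0,0010")
  if (!all(need %in% names(tags)))
    stop("DICOM file lacks required image tags: ",
         paste(setdiff(need, names(tags)), collapse = ", "))
  u16_of <- function(b) as.integer(b[1]) + 256L * as.integer(b[2])
  rows <- u16_of(tags[["0028,0010"]])
  cols <- u16_of(tags[["0028,0011"]])
  bits <- if (is.null(tags[["0028,0100"]])) 16L else u16_of(tags[["0028,0100"]])
  signed <- !is.null(tags[["0028,0103"]]) && u16_of(tags[["0028,0103"]]) == 1L
  slope <- if (is.null(tags[["0028,1053"]])) 1 else as.numeric(str_of(tags[["0028,1053"]]))
  intercept <- if (is.null(tags[["0028,1052"]])) 0 else as.numeric(str_of(tags[["0028,1052"]]))
  px_raw <- tags[["7fe0,0010"]]
  vals <- if (bits == 8L) {
    as.integer(px_raw)
  } else if (bits == 16L) {
    v <- readBin(px_raw, "integer", n = length(px_raw) %/% 2L, size = 2L,
                 signed = TRUE, endian = "little")
    if (!signed) { v[v < 0] <- v[v < 0] + 65536L }
    v
  } else stop("unsupported BitsAllocated: ", bits)
  if (length(vals) < rows * cols)
    stop("pixel data shorter than Rows x Columns")
  # DICOM pixel order is row-major (first row left to right)
  px <- matrix(vals[seq_len(rows * cols)], nrow = rows, ncol = cols,
               byrow = TRUE)
  list(pixels = px, slope = slope, intercept = intercept, bits = bits,
       signed = signed)
}
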
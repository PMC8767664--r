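# Minimal standalone FCS reader used as an independent oracle for the FCS
# writer: parses the 3.x header offsets and TEXT segment and decodes the
# float data block. Shares no code with the package writer.
read_fcs_oracle <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  ascii <- function(from, to) rawToChar(raw[from:to])
  version <- ascii(1, 6)
  text_begin <- as.integer(ascii(11, 18))
  text_end <- as.integer(ascii(19, 26))
  data_begin <- as.integer(ascii(27, 34))
  data_end <- as.integer(ascii(35, 42))
  text <- ascii(text_begin + 1L, text_end + 1L)   # offsets are 0-based
  delim <- substr(text, 1, 1)
  parts <- strsplit(substr(text, 2, nchar(text) - 1), delim,
                    fixed = TRUE)[[1]]
  kw <- setNames(parts[seq(2, length(parts), 2)],
                 parts[seq(1, length(parts), 2)])
  tot <- as.integer(kw[["$TOT"]]); par <- as.integer(kw[["$PAR"]])
  stopifnot(kw[["$DATATYPE"]] == "F", kw[["$BYTEORD"]] == "1,2,3,4")
  mat <- matrix(numeric(0), 0, par)
  if (tot > 0) {
    con <- rawConnection(raw[(data_begin + 1L):(data_end + 1L)])
    on.exit(close(con))
    vals <- readBin(con, "numeric", n = tot * par, size = 4L,
                    endian = "little")
    mat <- matrix(vals, nrow = tot, ncol = par, byrow = TRUE)
  }
  colnames(mat) <- vapply(seq_len(par), function(j) kw[[sprintf("$P%dN", j)]],
                          character(1))
  list(version = version, keywords = kw, data = mat)
}
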
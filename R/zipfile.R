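# Minimal ZIP archive writer (stored entries, no compression) with all
# member timestamps zeroed to the DOS epoch, so that re-exporting identical
# content yields a byte-identical archive. Readable by standard unzip tools
# and utils::unzip().

crc32_env <- new.env(parent = emptyenv())

# unsigned right shift on a 32-bit pattern held in an R integer
ushr1 <- function(x) {
  if (x >= 0L) return(bitwShiftR(x, 1L))
  bitwOr(bitwShiftR(bitwAnd(x, 2147483647L), 1L), 1073741824L)
}
ushr8 <- function(x) {
  for (i in 1:8) x <- ushr1(x)
  x
}

crc32_table_build <- function() {
  tab <- integer(256)
  for (n in 0:255) {
    c <- as.integer(n)
    for (k in 1:8) {
      c <- if (bitwAnd(c, 1L) != 0L) bitwXor(-306674912L, ushr1(c)) else ushr1(c)
    }
    tab[n + 1] <- c
  }
  tab
}

crc32 <- function(bytes) {
  if (is.null(crc32_env$tab)) crc32_env$tab <- crc32_table_build()
  tab <- crc32_env$tab
  c <- -1L  # 0xFFFFFFFF
  for (b in as.integer(bytes)) {
    c <- bitwXor(tab[bitwAnd(bitwXor(c, b), 255L) + 1L], ushr8(c))
  }
  bitwXor(c, -1L)
}

u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
u32 <- function(x) {
  # x may exceed .Machine$integer.max as a double; emit 4 little-endian bytes
  x <- as.numeric(x) %% 4294967296
  as.raw(c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256,
           (x %/% 16777216) %% 256))
}

crc32_unsigned <- function(bytes) {
  v <- crc32(bytes)
  if (v < 0) as.numeric(v) + 4294967296 else as.numeric(v)
}

#' Write a stored (uncompressed) ZIP archive
#'
#' @param path destination archive path.
#' @param files named list: member name -> raw vector or character scalar
#'   (written as UTF-8).
#' @return `path`, invisibly.
#' @keywords internal
write_zip <- function(path, files) {
  stopifnot(is.list(files), length(names(files)) == length(files))
  con <- file(path, "wb")
  on.exit(close(con))
  offsets <- numeric(length(files))
  central <- list()
  pos <- 0
  for (i in seq_along(files)) {
    name <- names(files)[i]
    data <- files[[i]]
    if (is.character(data)) data <- charToRaw(paste(data, collapse = "\n"))
    nm <- charToRaw(name)
    crc <- crc32_unsigned(data)
    sz <- length(data)
    local_hdr <- c(u32(67324752),        # local file header signature
                   u16(20), u16(0), u16(0),  # version, flags, method=store
                   u16(0), u16(33),      # mod time 00:00:00, date 1980-01-01
                   u32(crc), u32(sz), u32(sz),
                   u16(length(nm)), u16(0), nm)
    offsets[i] <- pos
    writeBin(local_hdr, con)
    writeBin(data, con)
    pos <- pos + length(local_hdr) + sz
    central[[i]] <- c(u32(33639248),     # central directory signature
                      u16(20), u16(20), u16(0), u16(0),
                      u16(0), u16(33),
                      u32(crc), u32(sz), u32(sz),
                      u16(length(nm)), u16(0), u16(0),
                      u16(0), u16(0), u32(0),
                      u32(offsets[i]), nm)
  }
  cd_start <- pos
  for (entry in central) writeBin(entry, con)
  cd_size <- sum(vapply(central, length, numeric(1)))
  eocd <- c(u32(101010256), u16(0), u16(0),
            u16(length(files)), u16(length(files)),
            u32(cd_size), u32(cd_start), u16(0))
  writeBin(eocd, con)
  invisible(path)
}
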
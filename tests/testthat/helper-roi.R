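## Independent ImageJ .roi writer used to create binary fixtures at test
## time, following the published ROI byte layout (header "Iout", version,
## type byte, bounding box, coordinate count, then x and y offsets as
## big-endian 16-bit integers relative to the bounding box).

write_ij_roi <- function(path, x, y, type = 0L) {
  ## ImageJ pixel coordinates: y grows downwards
  left <- floor(min(x)); top <- floor(min(y))
  xs <- as.integer(round(x - left)); ys <- as.integer(round(y - top))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("Iout", con, eos = NULL)
  wshort <- function(v) writeBin(as.integer(v), con, size = 2,
                                 endian = "big")
  wshort(227)                       # version
  writeBin(as.raw(c(type, 0)), con) # roi type + unused byte
  wshort(top); wshort(left)
  wshort(top + max(ys)); wshort(left + max(xs))
  wshort(length(xs))
  writeBin(raw(46), con)            # rest of the 64-byte header
  wshort(xs); wshort(ys)
  invisible(path)
}
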
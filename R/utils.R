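# fixed formatting for result tables: 6 significant digits, so identical
# runs produce byte-identical files
fmtNum <- function(x) {
  out <- formatC(x, digits = 6, format = "g")
  out[is.na(x)] <- "NA"
  out
}

writeResultTable <- function(d, path) {
  d <- as.data.frame(d)
  for (cn in colnames(d)) {
    if (is.numeric(d[[cn]])) d[[cn]] <- fmtNum(d[[cn]])
  }
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# FNV-1a string hash; used to fingerprint configurations in run logs
fnv1aHash <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(h, b)
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%08x", h)
}

logLines <- function(path, lines) {
  con <- file(path, "a")
  on.exit(close(con))
  writeLines(sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                     lines), con)
  invisible(path)
}
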
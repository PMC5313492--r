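# Fresh scratch directory per test; contents live under tempdir() and are
# cleaned up when the R session ends.
withr_local_tempdir <- function() {
  d <- tempfile("pettbi-test-")
  dir.create(d)
  d
}
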
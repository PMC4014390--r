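# Temp-file helper that cleans up at the end of the test run.

withr_local_tempfile <- function(ext = "") {
  f <- tempfile(fileext = ext)
  # deleted with the session tempdir; nothing to do
  f
}
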
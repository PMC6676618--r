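.onLoad <- function(libname, pkgname) {
  # ChemmineOB's compiled routines need Rcpp's DLL resident but its namespace
  # does not force the load; do it here.
  loadNamespace("Rcpp")
  invisible()
}
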
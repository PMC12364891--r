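# shared, lazily computed fixtures (the full phantom pipeline is the
# expensive one; it is run once per session and reused)
.fixtures <- new.env(parent = emptyenv())

phantom_fixture <- function() {
  if (is.null(.fixtures$phantom)) {
    ph <- make_phantom()
    out_dir <- file.path(tempdir(), "phantom_run1")
    res <- run_subject(ph$t1w, ph$labelmap, ph$wm_mask,
                       subject_id = "phantom", out_dir = out_dir)
    .fixtures$phantom <- list(ph = ph, res = res, out_dir = out_dir)
  }
  .fixtures$phantom
}

# cohort CSV on disk matching the subject-table schema
write_cohort_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, na = "")
  path
}
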
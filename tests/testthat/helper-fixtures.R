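# One shared fixture bundle per test run (seed-fixed). Generating the gene
# models and knowledge resources takes a few seconds; everything downstream
# reuses these objects.
if (!exists(".fx_env", inherits = TRUE)) {
  .fx_env <- new.env()
}
fx_bundle <- function() {
  if (is.null(.fx_env$fx)) {
    .fx_env$fx <- generate_fixture_bundle(
      dir = file.path(tempdir(), "oncoboard_fx_shared"),
      n_patients = 25, seed = 101)
  }
  .fx_env$fx
}
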
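# Bridge to the independent scipy oracle (inst/oracle/qlp_oracle.py).
# Each task: list(model = <irreversible EnzymeConstrainedModel>,
#                 problem = list(variant =, estot =, ...)).
# One python process solves all tasks of a batch.

modelAsList <- function(model) {
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  writeToyModel(model, path)
  jsonlite::fromJSON(path, simplifyVector = FALSE)
}

oracleSolve <- function(tasks) {
  script <- system.file("oracle", "qlp_oracle.py", package = "parrot")
  stopifnot(nzchar(script))
  bundles <- lapply(tasks, function(t)
    list(model = modelAsList(t$model), problem = t$problem))
  fin <- tempfile(fileext = ".json"); fout <- tempfile(fileext = ".json")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  jsonlite::write_json(bundles, fin, auto_unbox = TRUE, digits = NA,
                       null = "null")
  status <- system2("python", c(script, fin, fout),
                    stdout = TRUE, stderr = TRUE)
  if (!file.exists(fout))
    stop("oracle failed: ", paste(status, collapse = "\n"))
  jsonlite::fromJSON(fout, simplifyVector = FALSE)
}

# reference-distance problem description for a fixture
distanceProblem <- function(fx, variant, lambda = 0) {
  pr <- list(variant = variant, estot = fx$estot,
             eref = as.list(fx$eref@values),
             ereftot = allocationTotal(fx$eref))
  if (lambda > 0) {
    pr$lambda <- lambda
    pr$vref <- as.list(fx$vref)
  }
  pr
}
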
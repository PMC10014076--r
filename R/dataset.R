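#' Dose-response dataset
#'
#' The central container of the package: for one experimental condition
#' (receptor genotype x ligand x biological replicate), an ascending series of
#' stimulant doses, each holding the transformed single-cell outputs measured
#' at that dose. Doses form the input alphabet of the communication channel;
#' the per-cell outputs are draws from the channel's conditional output
#' distribution.
#'
#' @param doses numeric vector of non-negative doses, strictly increasing
#'   after sorting; may include a single unstimulated dose 0.
#' @param outputs list of numeric vectors, one per dose, each with at least
#'   one finite value on the declared transform scale.
#' @param receptor,ligand character condition labels.
#' @param replicate integer biological replicate index (>= 1).
#' @param transform_tag character tag recording the transform applied to the
#'   outputs (e.g. `"log10_floor"`, `"identity"`).
#' @param dose_unit character unit of the dose axis.
#'
#' @return an object of class `dose_response_dataset` with fields
#'   `condition` (list of receptor, ligand, replicate), `doses`, `outputs`,
#'   `transform_tag`, `dose_unit`.
#' @export
dose_response_dataset <- function(doses, outputs,
                                  receptor = "synthetic", ligand = "synthetic",
                                  replicate = 1L,
                                  transform_tag = "identity",
                                  dose_unit = "au") {
  doses <- as.numeric(doses)
  if (length(doses) < 1L) stop("at least one dose is required")
  if (anyNA(doses) || any(!is.finite(doses)) || any(doses < 0)) {
    stop("doses must be finite and non-negative")
  }
  if (anyDuplicated(doses)) stop("duplicate doses in dose series")
  if (!is.list(outputs) || length(outputs) != length(doses)) {
    stop("outputs must be a list with one element per dose")
  }
  ord <- order(doses)
  doses <- doses[ord]
  outputs <- outputs[ord]
  outputs <- lapply(outputs, as.numeric)
  n_i <- vapply(outputs, length, integer(1))
  if (any(n_i < 1L)) stop("every dose needs at least one cell")
  if (any(!vapply(outputs, function(v) all(is.finite(v)), logical(1)))) {
    stop("all outputs must be finite on the declared transform scale")
  }
  structure(
    list(
      condition = list(receptor = as.character(receptor),
                       ligand = as.character(ligand),
                       replicate = as.integer(replicate)),
      doses = doses,
      outputs = outputs,
      transform_tag = as.character(transform_tag),
      dose_unit = as.character(dose_unit)
    ),
    class = "dose_response_dataset"
  )
}

#' @export
print.dose_response_dataset <- function(x, ...) {
  cat("<dose_response_dataset> ",
      x$condition$receptor, " / ", x$condition$ligand,
      " / rep ", x$condition$replicate, "\n", sep = "")
  cat("  doses: ", length(x$doses), " (",
      format(min(x$doses)), " .. ", format(max(x$doses)), " ", x$dose_unit,
      ")\n", sep = "")
  cat("  cells/dose: ", paste(vapply(x$outputs, length, integer(1)),
                              collapse = ", "), "\n", sep = "")
  cat("  transform: ", x$transform_tag, "\n", sep = "")
  invisible(x)
}

#' Cells per dose
#' @param dataset a `dose_response_dataset`.
#' @return integer vector of per-dose cell counts.
#' @export
cells_per_dose <- function(dataset) {
  stopifnot(inherits(dataset, "dose_response_dataset"))
  vapply(dataset$outputs, length, integer(1))
}

#' Restrict a dataset to a prefix of its dose series
#'
#' Keeps the first `k` doses of the ascending series (the unstimulated dose,
#' when present, is always the first element and is therefore retained).
#'
#' @param dataset a `dose_response_dataset`.
#' @param k integer prefix length, 2 <= k <= number of doses.
#' @return a `dose_response_dataset` over the truncated dose series.
#' @export
restrict_doses <- function(dataset, k) {
  stopifnot(inherits(dataset, "dose_response_dataset"))
  k <- as.integer(k)
  if (k < 2L || k > length(dataset$doses)) {
    stop("prefix length must be between 2 and the number of doses")
  }
  dose_response_dataset(dataset$doses[seq_len(k)], dataset$outputs[seq_len(k)],
                        receptor = dataset$condition$receptor,
                        ligand = dataset$condition$ligand,
                        replicate = dataset$condition$replicate,
                        transform_tag = dataset$transform_tag,
                        dose_unit = dataset$dose_unit)
}

# Run `expr` with a private RNG stream seeded by `seed`, restoring the
# caller's .Random.seed afterwards so package functions never perturb the
# global stream.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}
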
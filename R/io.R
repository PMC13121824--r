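# Readers and writers: binary response matrices (CSV/TSV), fitted-model
# directories, and JSON model/design configuration.

#' Read a binary response matrix from CSV/TSV
#'
#' The file must have a header row; the delimiter is auto-detected from the
#' extension (\code{.tsv}/\code{.txt} = tab, otherwise comma). Cells must be
#' 0 or 1; missing values and non-binary cells are rejected with the
#' offending coordinates (missing responses are an explicit unsupported
#' feature, not silently imputed).
#'
#' @param path File path.
#' @return Numeric \code{N x J} matrix with column names from the header.
#' @export
read_response_matrix <- function(path) {
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path,
    header = TRUE, sep = sep, check.names = FALSE,
    colClasses = "character", na.strings = character(0)
  )
  if (anyDuplicated(names(df))) {
    stop("duplicate column names in ", path, call. = FALSE)
  }
  Xc <- as.matrix(df)
  Xc <- trimws(Xc)
  if (any(Xc %in% c("", "NA"))) {
    bad <- which(matrix(Xc %in% c("", "NA"), nrow(Xc)), arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "missing value at row %d, column '%s': missing responses are not supported",
      bad[1], colnames(Xc)[bad[2]]
    ), call. = FALSE)
  }
  nonbin <- which(!(Xc %in% c("0", "1")))
  if (length(nonbin)) {
    bad <- arrayInd(nonbin[1L], dim(Xc))
    stop(sprintf(
      "non-binary cell '%s' at row %d, column '%s'",
      Xc[bad], bad[1], colnames(Xc)[bad[2]]
    ), call. = FALSE)
  }
  X <- matrix(as.numeric(Xc), nrow = nrow(Xc),
    dimnames = list(NULL, colnames(Xc)))
  X
}

write_matrix_csv <- function(x, path, row_names = FALSE) {
  utils::write.csv(as.data.frame(x), path, row.names = row_names)
}

spec_to_list <- function(spec) {
  list(
    D = spec$D, widths = spec$widths,
    models = vapply(spec$layers, function(l) l$measurement_model, character(1)),
    links = vapply(spec$layers, function(l) l$link, character(1))
  )
}

spec_from_list <- function(x) {
  deepcdm_spec(
    J = x$widths[1], layers = x$widths[-1], models = x$models,
    links = x$links
  )
}

#' Read a DeepCDM architecture from a JSON file
#'
#' Expected keys: \code{widths} (\code{[J, K_1, ..., K_D]}), \code{models},
#' \code{links} (both recycled over layers).
#'
#' @param path JSON file path.
#' @return A [deepcdm_spec()].
#' @export
read_spec_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  deepcdm_spec(
    J = x$widths[1], layers = x$widths[-1],
    models = x$models %||% "main_effect",
    links = x$links %||% "inverse_logit"
  )
}

#' Write / read a fitted DeepCDM to a directory
#'
#' \code{write_fit()} serializes a \code{deepcdm_fit} as plain text: per
#' layer \code{B_layer<d>.csv}, \code{Q_layer<d>.csv}, \code{p_layer<d>.csv};
#' \code{pi.csv} (deepest proportions), \code{map_profiles.csv}, and
#' \code{provenance.json} carrying the seed, lambda grids, tolerances,
#' per-layer traces and BICs. \code{read_fit()} reconstructs the fit;
#' integers and flags round-trip exactly and reals to at least \code{1e-12}
#' relative accuracy.
#'
#' @param fit A \code{deepcdm_fit}.
#' @param dir Output directory.
#' @param force Overwrite an existing fit directory (default \code{FALSE}:
#'   refuse).
#' @return \code{write_fit()}: the directory, invisibly. \code{read_fit()}:
#'   a \code{deepcdm_fit} (without the response-dependent posterior fields
#'   recomputed unless data are supplied).
#' @export
write_fit <- function(fit, dir, force = FALSE) {
  stopifnot(inherits(fit, "deepcdm_fit"))
  if (dir.exists(dir) && file.exists(file.path(dir, "provenance.json"))) {
    if (!force) {
      stop("fit directory ", dir, " already exists; use force = TRUE to overwrite",
        call. = FALSE
      )
    }
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  D <- fit$spec$D
  for (d in seq_len(D)) {
    write_matrix_csv(fit$layers[[d]]$B, file.path(dir, sprintf("B_layer%d.csv", d)))
    if (!is.null(fit$Q[[d]])) {
      write_matrix_csv(fit$Q[[d]], file.path(dir, sprintf("Q_layer%d.csv", d)))
    }
    write_matrix_csv(
      data.frame(p = fit$p_hat[[d]]),
      file.path(dir, sprintf("p_layer%d.csv", d))
    )
  }
  write_matrix_csv(data.frame(pi = fit$params$pi), file.path(dir, "pi.csv"))
  write_matrix_csv(fit$map_profiles, file.path(dir, "map_profiles.csv"))
  meta <- list(
    spec = spec_to_list(fit$spec),
    bic = fit$bic, loglik = fit$loglik,
    provenance = fit$provenance,
    layers = lapply(fit$layers, function(f) {
      list(
        lambda = f$lambda, niter = f$niter, converged = f$converged,
        loglik = f$loglik, bic = f$bic, trace = f$trace, N = f$N,
        K = f$K, model = f$model
      )
    }),
    has_q = vapply(fit$Q, Negate(is.null), logical(1))
  )
  jsonlite::write_json(meta, file.path(dir, "provenance.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null"
  )
  invisible(dir)
}

#' @rdname write_fit
#' @export
read_fit <- function(dir) {
  pj <- file.path(dir, "provenance.json")
  need <- c("provenance.json", "pi.csv")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing)) {
    stop(
      "fit directory ", dir, " is incomplete; missing: ",
      paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  meta <- jsonlite::read_json(pj, simplifyVector = TRUE)
  spec <- spec_from_list(meta$spec)
  D <- spec$D
  need2 <- c(
    sprintf("B_layer%d.csv", seq_len(D)),
    sprintf("p_layer%d.csv", seq_len(D))
  )
  missing2 <- need2[!file.exists(file.path(dir, need2))]
  if (length(missing2)) {
    stop(
      "fit directory ", dir, " is incomplete; missing: ",
      paste(missing2, collapse = ", "),
      call. = FALSE
    )
  }
  layer_meta <- meta$layers
  layers <- vector("list", D)
  Q <- vector("list", D)
  p_hat <- vector("list", D)
  for (d in seq_len(D)) {
    B <- as.matrix(utils::read.csv(file.path(dir, sprintf("B_layer%d.csv", d)),
      check.names = FALSE
    ))
    lm_d <- if (is.data.frame(layer_meta)) lapply(layer_meta, `[[`, d) else layer_meta[[d]]
    p_hat[[d]] <- utils::read.csv(file.path(dir, sprintf("p_layer%d.csv", d)))$p
    qd_path <- file.path(dir, sprintf("Q_layer%d.csv", d))
    if (file.exists(qd_path)) {
      Q[[d]] <- as.matrix(utils::read.csv(qd_path, check.names = FALSE))
    }
    pis <- if (d == D) {
      utils::read.csv(file.path(dir, "pi.csv"))$pi
    } else {
      p_hat[[d]]
    }
    layers[[d]] <- structure(
      list(
        B = B, pi = pis, lambda = lm_d$lambda, trace = unlist(lm_d$trace),
        niter = lm_d$niter, converged = lm_d$converged, loglik = lm_d$loglik,
        N = lm_d$N, K = lm_d$K, model = lm_d$model,
        basis = fitting_basis(lm_d$model, lm_d$K), bic = lm_d$bic
      ),
      class = "layer_fit"
    )
  }
  params <- deepcdm_params(spec,
    B = lapply(layers, function(f) f$B), Q = Q,
    pi = layers[[D]]$pi / sum(layers[[D]]$pi)
  )
  structure(
    list(
      spec = spec, layers = layers, Q = Q, params = params, p_hat = p_hat,
      posterior1 = NULL,
      map_profiles = as.matrix(utils::read.csv(file.path(dir, "map_profiles.csv"))),
      bic = meta$bic, loglik = meta$loglik, provenance = meta$provenance
    ),
    class = "deepcdm_fit"
  )
}

design_to_list <- function(design) {
  list(
    case = design$case, N = design$N, seed = design$seed,
    slopes = design$slopes, spec = spec_to_list(design$spec),
    Q = design$Q, B = design$B, pi = design$pi
  )
}

#' Write / read a simulation design (full truth) as JSON
#'
#' @param design A [make_design()] object.
#' @param path JSON file path.
#' @return \code{read_design_json()} returns the reconstructed
#'   \code{deepcdm_design}.
#' @export
write_design_json <- function(design, path) {
  jsonlite::write_json(design_to_list(design), path,
    auto_unbox = TRUE,
    digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' @rdname write_design_json
#' @export
read_design_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  widths <- x$spec$widths
  make_design(
    case = x$case, N = x$N, seed = x$seed, widths = widths,
    slopes = x$slopes,
    Q = lapply(x$Q, as.matrix), B = lapply(x$B, as.matrix),
    pi = x$pi
  )
}
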
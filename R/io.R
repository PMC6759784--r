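# Delimited-file readers and writers, and key-value configuration loading.
# Format: UTF-8 comma-separated with a mandatory header row, "." decimal,
# optional "#"-prefixed header comment lines.

.EVIDENCE_SCHEMAS <- list(
  z = c("z"),
  p = c("p"),
  ratio = c("estimate", "ci_lower", "ci_upper"))

#' Read an evidence table
#'
#' Accepts one of three column schemas next to a \code{test_id} column:
#' \code{z}; \code{p}; or \code{estimate, ci_lower, ci_upper} (ratio scale,
#' converted to z via the log-ratio and its Wald SE).  Mixed or unknown
#' schemas are errors.
#'
#' @param path path to a CSV file.
#' @param level CI coverage for the ratio schema; default 0.95.
#' @return a list with \code{evidence} (an \code{\link{evidence_vector}}),
#'   \code{meta} (the full data.frame as read), and \code{schema}.
#' @export
read_evidence <- function(path, level = 0.95) {
  if (!file.exists(path)) stop(sprintf("file '%s' does not exist", path))
  df <- tryCatch(
    utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                    encoding = "UTF-8"),
    error = function(e) stop(sprintf("cannot read '%s': %s", path,
                                     conditionMessage(e)), call. = FALSE))
  if (nrow(df) == 0L) stop(sprintf("'%s' contains no data rows", path))
  if (!"test_id" %in% names(df)) stop("missing required column 'test_id'")
  present <- vapply(.EVIDENCE_SCHEMAS, function(cols) all(cols %in% names(df)),
                    logical(1))
  if (sum(present) == 0L)
    stop("no recognized schema: need column 'z', 'p', or ",
         "'estimate','ci_lower','ci_upper'")
  if (sum(present) > 1L)
    stop("mixed schemas: supply exactly one of z / p / estimate+CI")
  schema <- names(.EVIDENCE_SCHEMAS)[present]
  cols <- .EVIDENCE_SCHEMAS[[schema]]
  for (cl in cols) {
    v <- suppressWarnings(as.numeric(df[[cl]]))
    bad <- which(is.na(v) & !is.na(df[[cl]]))
    if (any(is.na(v)))
      stop(sprintf("non-numeric cell in column '%s', row %d", cl,
                   c(bad, which(is.na(v)))[1]))
    df[[cl]] <- v
  }
  ev <- switch(schema,
    z = evidence_vector(df$z, scale = "z"),
    p = evidence_vector(df$p, scale = "p"),
    ratio = {
      se <- mapply(function(e, lo, hi)
        se_from_ci(ratio_estimate(e, lo, hi, level = level)),
        df$estimate, df$ci_lower, df$ci_upper)
      evidence_vector(log(df$estimate), scale = "log_ratio_with_se", se = se)
    })
  list(evidence = ev, meta = df, schema = schema)
}

#' Write a result table with a reproducibility header
#'
#' Writes "#"-prefixed header lines (package version, resolved
#' configuration, seed -- whatever the caller supplies) followed by a CSV
#' body.  Numeric values are written at 15 significant digits so that a
#' write/read round-trip is lossless.
#'
#' @param path output path.
#' @param table a data.frame.
#' @param header character vector of header lines (without the leading
#'   \code{"# "}).
#' @return invisibly, \code{path}.
#' @export
write_results <- function(path, table, header = character()) {
  stopifnot(is.data.frame(table))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (length(header))
    writeLines(paste("#", header), con)
  fmt <- table
  num <- vapply(fmt, is.numeric, logical(1))
  fmt[num] <- lapply(fmt[num], function(v) sprintf("%.15g", v))
  utils::write.csv(fmt, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load and validate a configuration file
#'
#' The configuration is a YAML key-value document with up to three blocks:
#' \code{prior} (tagged by \code{kind}: independent / common_cause /
#' explicit / pairwise), \code{evidence} (scale, mu or a, residual
#' correlation r), and \code{scenario} (simulator parameters).  Every
#' block's validation runs; all violations are collected and reported
#' together rather than stopping at the first.
#'
#' @param path path to a YAML file.
#' @param K number of tests, required when the prior block does not imply
#'   it (e.g. common_cause); may also be given in the file.
#' @return a list with any of \code{prior}, \code{model}, \code{scenario}.
#' @export
load_config <- function(path, K = NULL) {
  if (!file.exists(path)) stop(sprintf("file '%s' does not exist", path))
  cfg <- yaml::read_yaml(path)
  errors <- character()
  collect <- function(label, expr) {
    tryCatch(expr, error = function(e) {
      errors <<- c(errors, sprintf("%s: %s", label, conditionMessage(e)))
      NULL
    })
  }
  if (!is.null(cfg$K)) K <- cfg$K
  prior <- NULL
  if (!is.null(cfg$prior)) {
    pb <- cfg$prior
    prior <- collect("prior", {
      kind <- pb$kind
      if (is.null(kind)) stop("missing 'kind'")
      switch(kind,
        independent = independent_prior(unlist(pb$pi)),
        common_cause = {
          if (is.null(K)) stop("common_cause prior requires K")
          common_cause_prior(pb$pi, pb$rho, K)
        },
        explicit = {
          mass <- unlist(pb$mass)
          s <- sum(mass)
          if (abs(s - 1) > 1e-12)
            stop(sprintf("explicit prior table sums to %.15g, not 1", s))
          explicit_prior(mass)
        },
        pairwise = pairwise_prior(pb$pi_f, pb$pi_m, pb$rho),
        stop(sprintf("unknown prior kind '%s'", kind)))
    })
    if (!is.null(prior)) K <- prior$K
  }
  model <- NULL
  if (!is.null(cfg$evidence)) {
    eb <- cfg$evidence
    model <- collect("evidence", {
      if (is.null(K)) stop("evidence block requires K")
      scale <- if (is.null(eb$scale)) "z" else eb$scale
      R <- if (!is.null(eb$r) && eb$r != 0) equicorrelation(K, eb$r) else NULL
      evidence_model(K, scale = scale,
                     mu = if (is.null(eb$mu)) 2 else unlist(eb$mu),
                     a = if (is.null(eb$a)) 0.1 else unlist(eb$a),
                     R = R)
    })
  }
  scenario <- NULL
  if (!is.null(cfg$scenario)) {
    sb <- cfg$scenario
    # YAML 1.1 reads a bare key "N" as the boolean FALSE; map it back
    names(sb)[names(sb) == "FALSE"] <- "N"
    scenario <- collect("scenario", {
      args <- sb[names(sb) %in% names(formals(scenario_spec))]
      do.call(scenario_spec, args)
    })
  }
  if (length(errors))
    stop("configuration errors:\n  ", paste(errors, collapse = "\n  "))
  list(prior = prior, model = model, scenario = scenario, K = K)
}
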
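#' Longitudinal panel container
#'
#' Holds persons x occasion matrices for a set of role-tagged variables on a
#' fixed time grid `t_0..t_K` shared by all persons. Missing cells are `NA`
#' (flagged, never imputed). The causal ordering within an occasion is
#' confounders before treatment: `L_0, A_0, L_1, A_1, ..., L_K`. Variables may
#' have different occasion sets (e.g. a treatment defined only at `0..K-1`).
#'
#' @param values named list of numeric matrices (persons x occasions); column
#'   names `"t0", "t1", ...` declare each variable's occasions (defaulting to
#'   `t0..t(ncol-1)` when absent).
#' @param roles list with entries `outcome` (one name), `treatment` (one
#'   name) and `confounders` (zero or more names), referring to `values`.
#' @param K highest occasion index on the grid; inferred when missing.
#' @param person_id optional person identifiers (default `1..N`).
#' @return object of class `"panel_data"`.
#' @export
panel_data <- function(values, roles, K = NULL, person_id = NULL) {
  if (!length(values)) .stopf("no variables supplied")
  N <- unique(vapply(values, nrow, integer(1)))
  if (length(N) != 1) .stopf("all variables must cover the same persons")
  values <- lapply(values, function(m) {
    m <- as.matrix(m)
    if (is.null(colnames(m))) colnames(m) <- paste0("t", seq_len(ncol(m)) - 1)
    storage.mode(m) <- "double"
    m
  })
  waves <- lapply(values, function(m) as.integer(sub("^t", "", colnames(m))))
  if (is.null(K)) K <- max(unlist(waves))
  need <- c(roles$outcome, roles$treatment, roles$confounders)
  miss <- setdiff(need, names(values))
  if (length(miss)) .stopf("role refers to unknown variable(s): %s",
                           paste(miss, collapse = ", "))
  if (length(roles$outcome) != 1 || length(roles$treatment) != 1)
    .stopf("exactly one outcome and one treatment must be named")
  if (is.null(person_id)) person_id <- seq_len(N)
  obs <- Reduce(`+`, lapply(values, function(m) rowSums(!is.na(m))))
  if (any(obs == 0)) {
    .warnf("dropping %d person(s) with no observed values", sum(obs == 0))
    keep <- obs > 0
    values <- lapply(values, function(m) m[keep, , drop = FALSE])
    person_id <- person_id[keep]
  }
  structure(list(values = values, waves = waves, roles = roles,
                 K = as.integer(K), person_id = person_id),
            class = "panel_data")
}

#' @export
print.panel_data <- function(x, ...) {
  cat(sprintf("panel_data: %d persons, grid t0..t%d, %d variables\n",
              length(x$person_id), x$K, length(x$values)))
  for (v in names(x$values)) {
    role <- if (v == x$roles$outcome) "outcome"
    else if (v == x$roles$treatment) "treatment"
    else if (v %in% x$roles$confounders) "confounder" else "extra"
    cat(sprintf("  %s [%s]: occasions %s, %.1f%% missing\n", v, role,
                paste(range(x$waves[[v]]), collapse = ".."),
                100 * mean(is.na(x$values[[v]]))))
  }
  invisible(x)
}

#' Read a longitudinal panel from CSV
#'
#' @param path CSV file. Long layout needs columns `person`, `time`,
#'   `variable`, `value`; wide layout needs a `person` column plus
#'   `<variable><separator><time>` columns (e.g. `Y_0`).
#' @param schema role mapping: a list (or path to a YAML/JSON file holding
#'   one) with `outcome`, `treatment`, `confounders`, and optionally `layout`
#'   (`"long"` or `"wide"`) and `separator` (wide layout, default `"_"`).
#' @param layout overrides the schema's layout.
#' @return a [panel_data()].
#' @export
read_panel <- function(path, schema, layout = NULL) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  if (is.character(schema)) schema <- .read_config(schema)
  layout <- layout %||% schema$layout %||% "long"
  sep <- schema$separator %||% "_"
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) .stopf("no records in %s", path)
  if (layout == "long") {
    need <- c("person", "time", "variable", "value")
    miss <- setdiff(need, names(df))
    if (length(miss)) .stopf("long layout missing column(s): %s",
                             paste(miss, collapse = ", "))
    persons <- unique(df$person)
    values <- list()
    for (v in unique(df$variable)) {
      dv <- df[df$variable == v, ]
      waves <- sort(unique(dv$time))
      m <- matrix(NA_real_, length(persons), length(waves),
                  dimnames = list(NULL, paste0("t", waves)))
      m[cbind(match(dv$person, persons), match(dv$time, waves))] <- dv$value
      values[[v]] <- m
    }
  } else if (layout == "wide") {
    if (!"person" %in% names(df)) .stopf("wide layout needs a 'person' column")
    persons <- df$person
    cols <- setdiff(names(df), "person")
    pat <- paste0("^(.*)", ifelse(sep == ".", "\\.", sep), "([0-9]+)$")
    ok <- grepl(pat, cols)
    if (any(!ok)) .stopf("unknown column(s) for wide layout: %s",
                         paste(cols[!ok], collapse = ", "))
    vars <- sub(pat, "\\1", cols)
    waves <- as.integer(sub(pat, "\\2", cols))
    values <- list()
    for (v in unique(vars)) {
      idx <- which(vars == v)
      idx <- idx[order(waves[idx])]
      m <- as.matrix(df[, cols[idx], drop = FALSE])
      colnames(m) <- paste0("t", sort(waves[vars == v]))
      values[[v]] <- m
    }
  } else .stopf("layout must be 'long' or 'wide'")
  roles <- list(outcome = schema$outcome, treatment = schema$treatment,
                confounders = as.character(schema$confounders %||% character(0)))
  # the grid must be rectangular: every variable observed (possibly NA) on a
  # contiguous 0-based wave set shared across persons
  for (v in names(values)) {
    w <- as.integer(sub("^t", "", colnames(values[[v]])))
    if (!identical(w, seq.int(min(w), max(w))))
      .stopf("non-rectangular time grid for variable %s", v)
  }
  panel_data(values, roles, person_id = persons)
}

#' Write a panel to long-format CSV
#'
#' Inverse of [read_panel()] with a long layout; missing cells are omitted.
#'
#' @param panel a [panel_data()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  rows <- do.call(rbind, lapply(names(panel$values), function(v) {
    m <- panel$values[[v]]
    idx <- which(!is.na(m), arr.ind = TRUE)
    data.frame(person = panel$person_id[idx[, 1]],
               time = panel$waves[[v]][idx[, 2]],
               variable = v, value = m[idx])
  }))
  rows <- rows[order(rows$person, rows$variable, rows$time), ]
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write predicted scores to long-format CSV
#'
#' One row per observed person/occasion/variable cell with the predicted
#' within-person score and the person's stable-trait prediction; cells with
#' missing scores are omitted, so the row count matches the observation mask.
#'
#' @param scores a `score_set` (see [predict_scores()]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path) {
  rows <- do.call(rbind, lapply(names(scores$within), function(v) {
    m <- scores$within[[v]]
    idx <- which(!is.na(m), arr.ind = TRUE)
    st <- if (!is.null(scores$stable) && v %in% colnames(scores$stable))
      scores$stable[idx[, 1], v] else NA_real_
    data.frame(person = scores$person_id[idx[, 1]],
               time = scores$waves[[v]][idx[, 2]],
               variable = v, within_score = m[idx], stable_trait = st)
  }))
  rows <- rows[order(rows$person, rows$variable, rows$time), ]
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read scores written by [write_scores()]
#'
#' @param path CSV produced by [write_scores()].
#' @return list with `within` (list of person x occasion matrices), `stable`
#'   (person x variable matrix), `person_id` and `waves`.
#' @export
read_scores <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  persons <- unique(df$person)
  within <- list(); stable <- list(); waves <- list()
  for (v in unique(df$variable)) {
    dv <- df[df$variable == v, ]
    w <- sort(unique(dv$time))
    m <- matrix(NA_real_, length(persons), length(w),
                dimnames = list(NULL, paste0("t", w)))
    m[cbind(match(dv$person, persons), match(dv$time, w))] <- dv$within_score
    within[[v]] <- m
    waves[[v]] <- w
    s <- rep(NA_real_, length(persons))
    s[match(dv$person, persons)] <- dv$stable_trait
    stable[[v]] <- s
  }
  list(within = within,
       stable = do.call(cbind, stable),
       person_id = persons, waves = waves)
}

#' Validation report for a panel
#'
#' Report-only diagnostics: per-variable missing rates, per-person observed
#' counts, and constant-column warnings. Never mutates the panel.
#'
#' @param panel a [panel_data()].
#' @return list of class `"panel_report"` with `missing_rate` (per variable),
#'   `observed_counts` (per person, across all variables), and
#'   `constant_columns` (variable/occasion labels with zero variance).
#' @export
validate_panel <- function(panel) {
  missing_rate <- vapply(panel$values, function(m) mean(is.na(m)), numeric(1))
  observed <- Reduce(`+`, lapply(panel$values, function(m) rowSums(!is.na(m))))
  const <- character(0)
  for (v in names(panel$values)) {
    m <- panel$values[[v]]
    sds <- apply(m, 2, stats::sd, na.rm = TRUE)
    bad <- which(!is.na(sds) & sds == 0)
    if (length(bad)) const <- c(const, paste0(v, ":", colnames(m)[bad]))
  }
  structure(list(missing_rate = missing_rate,
                 observed_counts = stats::setNames(observed, panel$person_id),
                 constant_columns = const),
            class = "panel_report")
}

#' @export
print.panel_report <- function(x, ...) {
  cat("panel validation report\n  missing rates:\n")
  for (v in names(x$missing_rate))
    cat(sprintf("    %s: %.1f%%\n", v, 100 * x$missing_rate[v]))
  cat(sprintf("  persons: %d, observed cells per person %d..%d\n",
              length(x$observed_counts), min(x$observed_counts),
              max(x$observed_counts)))
  if (length(x$constant_columns))
    cat("  constant columns:", paste(x$constant_columns, collapse = ", "), "\n")
  invisible(x)
}

.read_config <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    # keep the YAML-1.1 boolean-like single letters Y/N as literal strings
    # (they are legitimate variable names and config keys here); longer
    # forms (yes/no/true/false) stay booleans
    keep <- function(value) {
      function(x) if (nchar(x) == 1) x else value
    }
    yaml::read_yaml(path, handlers = list(`bool#yes` = keep(TRUE),
                                          `bool#no` = keep(FALSE)))
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
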
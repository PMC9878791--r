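#' Phenotyping table with declared variable roles
#'
#' The central container of the package: individuals in rows, recorded
#' variables in columns, each variable carrying a role (`dependent`,
#' `conditioning` or `predictor`), a type (`quantitative` or `qualitative`)
#' and an optional group label (several readouts of the same behavioural test
#' share a group). A per-cell logical mask records which values were imputed;
#' it is all-`FALSE` on load.
#'
#' @param data data.frame of variable columns (no id column).
#' @param ids Character vector of individual identifiers, one per row.
#' @param var_roles,var_types,var_groups Named character vectors over
#'   `names(data)`; `var_groups` entries may be `NA` (ungrouped; treated
#'   downstream as singleton groups).
#' @return An object of class `pheno_table`.
#' @export
pheno_table <- function(data, ids, var_roles, var_types, var_groups = NULL) {
  stopifnot(is.data.frame(data), nrow(data) == length(ids))
  vars <- names(data)
  if (is.null(var_groups)) var_groups <- stats::setNames(rep(NA_character_, length(vars)), vars)
  x <- structure(list(
    data = data,
    ids = as.character(ids),
    var_roles = var_roles[vars],
    var_types = var_types[vars],
    var_groups = var_groups[vars],
    imputed = matrix(FALSE, nrow(data), ncol(data),
                     dimnames = list(NULL, vars)),
    scaling = NULL,
    id_mapping = NULL,
    imputation_log = NULL
  ), class = "pheno_table")
  validate_pheno_table(x)
}

validate_pheno_table <- function(x) {
  vars <- names(x$data)
  roles <- x$var_roles
  if (anyNA(roles) || !all(roles %in% c("dependent", "conditioning", "predictor"))) {
    stop("pd_bad_roles: every variable needs exactly one role in {dependent, conditioning, predictor}")
  }
  if (sum(roles == "dependent") != 1L) {
    stop("pd_no_dependent: exactly one dependent variable is required")
  }
  dep <- vars[roles == "dependent"]
  if (x$var_types[[dep]] != "qualitative") {
    stop("pd_bad_dependent: the dependent variable must be qualitative")
  }
  if (length(unique(stats::na.omit(x$data[[dep]]))) < 2L) {
    stop("pd_degenerate_dependent: dependent variable has fewer than 2 levels")
  }
  if (anyNA(x$var_types) || !all(x$var_types %in% c("quantitative", "qualitative"))) {
    stop("pd_bad_types: every variable needs a type in {quantitative, qualitative}")
  }
  bad <- vars[(x$var_types == "quantitative") & !vapply(x$data, is.numeric, TRUE)]
  if (length(bad)) stop("pd_bad_types: non-numeric storage for quantitative ", paste(bad, collapse = ", "))
  x
}

#' @export
print.pheno_table <- function(x, ...) {
  cat(sprintf("pheno_table: %d individuals x %d variables\n",
              nrow(x$data), ncol(x$data)))
  cat("  dependent:   ", dependent_var(x), "\n")
  cond <- names(x$var_roles)[x$var_roles == "conditioning"]
  cat("  conditioning:", if (length(cond)) paste(cond, collapse = ", ") else "(none)", "\n")
  cat(sprintf("  predictors:   %d quantitative, %d qualitative\n",
              sum(x$var_roles == "predictor" & x$var_types == "quantitative"),
              sum(x$var_roles == "predictor" & x$var_types == "qualitative")))
  cat(sprintf("  missing cells: %d; imputed cells: %d\n",
              sum(is.na(as.matrix(x$data))), sum(x$imputed)))
  invisible(x)
}

dependent_var <- function(x) names(x$var_roles)[x$var_roles == "dependent"]

predictor_vars <- function(x, type = NULL) {
  v <- names(x$var_roles)[x$var_roles == "predictor"]
  if (!is.null(type)) v <- v[x$var_types[v] == type]
  v
}

conditioning_vars <- function(x) names(x$var_roles)[x$var_roles == "conditioning"]

#' Subset the variables of a pheno_table
#'
#' Keeps row order and per-cell imputation provenance; the dependent variable
#' is always retained.
#' @param x A [pheno_table].
#' @param vars Variable names to keep (the dependent is added if absent).
#' @return A `pheno_table`.
#' @export
keep_vars <- function(x, vars) {
  vars <- union(vars, dependent_var(x))
  vars <- names(x$data)[names(x$data) %in% vars]   # preserve column order
  x$data <- x$data[, vars, drop = FALSE]
  x$var_roles <- x$var_roles[vars]
  x$var_types <- x$var_types[vars]
  x$var_groups <- x$var_groups[vars]
  x$imputed <- x$imputed[, vars, drop = FALSE]
  if (!is.null(x$scaling)) x$scaling <- lapply(x$scaling, function(s) s[names(s) %in% vars])
  x
}

#' Split a column header into group label and variable name
#'
#' Headers may encode a test-group label with a `"::"` separator, e.g.
#' `"HotPlate50::Latency"` names variable `Latency` in group `HotPlate50`.
#'
#' @param header A single non-empty header string.
#' @return List with elements `group` (`NA` when ungrouped) and `variable`.
#' @examples
#' parse_group_label("Acetone::NbReactions")
#' parse_group_label("vonFrey")
#' @export
parse_group_label <- function(header) {
  stopifnot(is.character(header), length(header) == 1L, nzchar(header))
  parts <- strsplit(header, "::", fixed = TRUE)[[1]]
  n_sep <- lengths(regmatches(header, gregexpr("::", header, fixed = TRUE)))
  if (n_sep > 1L) stop("pd_ambiguous_header: more than one '::' in '", header, "'")
  if (n_sep == 0L) return(list(group = NA_character_, variable = header))
  if (length(parts) != 2L || !all(nzchar(parts))) {
    stop("pd_ambiguous_header: empty group or variable part in '", header, "'")
  }
  list(group = parts[[1]], variable = parts[[2]])
}

infer_type <- function(col, na_strings) {
  if (is.numeric(col)) return("quantitative")
  v <- as.character(col)
  v[v %in% na_strings] <- NA
  v <- v[!is.na(v)]
  if (!length(v)) return("qualitative")
  parsed <- suppressWarnings(as.numeric(v))
  if (mean(!is.na(parsed)) >= 0.9) "quantitative" else "qualitative"
}

#' Read a phenotyping table from XLSX or CSV/TSV
#'
#' Individuals in rows, variables in columns, mandatory header row. Column
#' headers may carry `"group::variable"` labels (see [parse_group_label()]).
#' Types are inferred (a column is quantitative when at least 90% of its
#' non-missing cells parse as numbers) unless overridden in the config; the
#' dependent and conditioning columns are declared in the config, never
#' guessed. Missing cells stay missing — they are never coerced to zero.
#'
#' @param path Path to an `.xlsx`, `.csv` or `.tsv`/`.txt` file.
#' @param config A [pd_config()]; its `dependent`, `id`, `conditioning`,
#'   `na_strings`, `type_overrides` and `sheet` fields are used.
#' @return A [pheno_table].
#' @export
read_pheno_table <- function(path, config) {
  if (!file.exists(path)) stop("pd_unreadable_file: no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    xlsx = as.data.frame(readxl::read_excel(
      path, sheet = if (is.null(config$sheet)) 1L else config$sheet,
      col_types = "text", .name_repair = "minimal")),
    csv = utils::read.csv(path, check.names = FALSE, colClasses = "character"),
    tsv = ,
    txt = utils::read.delim(path, check.names = FALSE, colClasses = "character"),
    stop("pd_unreadable_file: unsupported extension '", ext, "'")
  )
  parsed <- lapply(names(raw), parse_group_label)
  vars <- vapply(parsed, `[[`, "", "variable")
  groups <- vapply(parsed, `[[`, "", "group")
  if (anyDuplicated(vars)) {
    stop("pd_duplicate_columns: duplicated variable names after group stripping: ",
         paste(unique(vars[duplicated(vars)]), collapse = ", "))
  }
  names(raw) <- vars
  for (v in vars) raw[[v]][raw[[v]] %in% config$na_strings] <- NA

  if (!is.null(config$id)) {
    if (!config$id %in% vars) stop("pd_no_id_column: id column '", config$id, "' not found")
    ids <- as.character(raw[[config$id]])
    keep <- setdiff(vars, config$id)
    groups <- groups[match(keep, vars)]
    raw <- raw[, keep, drop = FALSE]
    vars <- keep
  } else {
    ids <- sprintf("IND%03d", seq_len(nrow(raw)))
  }
  if (!config$dependent %in% vars) {
    stop("pd_no_dependent: dependent column '", config$dependent, "' not found")
  }
  missing_cond <- setdiff(config$conditioning, vars)
  if (length(missing_cond)) {
    stop("pd_no_dependent: conditioning column(s) not found: ",
         paste(missing_cond, collapse = ", "))
  }

  types <- vapply(vars, function(v) infer_type(raw[[v]], config$na_strings), "")
  types[names(config$type_overrides)] <- config$type_overrides
  types[[config$dependent]] <- "qualitative"
  for (v in vars[types == "quantitative"]) {
    raw[[v]] <- suppressWarnings(as.numeric(raw[[v]]))
  }
  roles <- stats::setNames(rep("predictor", length(vars)), vars)
  roles[[config$dependent]] <- "dependent"
  roles[config$conditioning] <- "conditioning"

  pheno_table(raw, ids, roles, stats::setNames(types, vars),
              stats::setNames(groups, vars))
}

#' Write a pheno_table (and sidecars) as TSV
#'
#' The value table round-trips through [read_pheno_table()]: group labels are
#' re-encoded into the headers. Roles/types are written to a `.schema.tsv`
#' sidecar and the anonymization mapping, when present, to a `.ids.tsv`
#' sidecar.
#'
#' @param x A [pheno_table].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_pheno_table <- function(x, path) {
  vars <- names(x$data)
  headers <- ifelse(is.na(x$var_groups), vars,
                    paste0(x$var_groups, "::", vars))
  out <- cbind(data.frame(id = x$ids, stringsAsFactors = FALSE), x$data)
  names(out) <- c("id", headers)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  schema <- data.frame(variable = vars, role = unname(x$var_roles),
                       type = unname(x$var_types),
                       group = unname(x$var_groups))
  utils::write.table(schema, paste0(path, ".schema.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(x$id_mapping)) {
    utils::write.table(x$id_mapping, paste0(path, ".ids.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Anonymize individual identifiers
#'
#' Replaces every identifier with a generated unique `IND###` key and returns
#' the old/new mapping as a sidecar (kept on the table, written only on
#' request). Two rows are reported as true duplicates only when both the
#' identifier and all conditioning values coincide; rows that share an id but
#' differ in conditioning stratum are distinct individuals that were keyed
#' ambiguously. Either way every row receives a unique id. Idempotent.
#'
#' @param x A [pheno_table].
#' @param conditioning Conditioning variable names (defaults to the table's
#'   declared conditioning variables plus the dependent).
#' @return The table with new ids; mapping in `$id_mapping`.
#' @export
anonymize_ids <- function(x, conditioning = NULL) {
  if (is.null(conditioning)) {
    conditioning <- c(conditioning_vars(x), dependent_var(x))
  }
  missing <- setdiff(conditioning, names(x$data))
  if (length(missing)) stop("pd_bad_roles: unknown conditioning variable(s): ",
                            paste(missing, collapse = ", "))
  strata <- do.call(paste, c(lapply(conditioning, function(v) as.character(x$data[[v]])),
                             sep = "\r"))
  dup <- duplicated(paste(x$ids, strata, sep = "\r"))
  new_ids <- sprintf("IND%03d", seq_along(x$ids))
  mapping <- data.frame(original = x$ids, anonymized = new_ids,
                        duplicate_of_earlier_row = dup,
                        stringsAsFactors = FALSE)
  x$ids <- new_ids
  x$id_mapping <- mapping
  x
}
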
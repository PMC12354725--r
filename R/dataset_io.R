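#' Canonical reaction-table columns
#'
#' The package stores one reaction trial per row ("long/flat" layout): a trial
#' is one run of a catalytic cross-coupling reaction at one catalyst reuse
#' cycle. Two-step reactions keep both steps on the same row, with per-step
#' quantity columns suffixed `_s1`/`_s2`. The canonical columns are:
#'
#' * `reaction_id` — opaque trial identifier (character).
#' * `reaction_type` — one of `suzuki_miyaura`, `kumada`, `negishi`,
#'   `buchwald_hartwig`, `csp2_h`, `csp3_h`, `double_carbonylation`.
#' * `reuse_cycle` — integer `n >= 0`; 0 means first use of the catalyst.
#' * `yield_pct` — observed yield in `[0, 100]`, `NA` when unreported.
#' * `nucleophile_step_code` — integer code in `{0,1,2,3}` (see
#'   [encode_nucleophile_step()]); may be `NA` before encoding. Distinct from
#'   the nucleophile role's step tag column `nucleophile_step`.
#' * `intramolecular` — logical; intramolecular reactions have no separate
#'   nucleophile addition and encode as step code 0.
#' * `split_label` — `"t"` (training), `"v"` (validation) or `"unassigned"`.
#' * `c_1` ... `c_9` — qualitative condition labels: catalyst nature, support
#'   type, support form, metal, preparation process, support treatment,
#'   assembly-procedure generation, reaction type (mirrors `reaction_type`),
#'   yield detection method.
#' * per role in `catalyst`, `electrophile`, `nucleophile`, `solvent`, `base`:
#'   `<role>_id`, `<role>_qty_s1`, `<role>_qty_s2`, `<role>_unit`,
#'   `<role>_step` (`"1"`, `"2"`, `"both"`, `"n/a"`).
#'
#' Missing values are empty cells on disk and `NA` in memory; imputation is an
#' explicit later stage ([impute_group_mean()]). Molecule identity is an opaque
#' `molecule_id`; an optional `smiles` column is carried as metadata only.
#'
#' @return `reaction_columns()` returns the canonical column names in order.
#' @export
reaction_columns <- function() {
  role_cols <- unlist(lapply(.ptml_roles, function(r) {
    paste0(r, c("_id", "_qty_s1", "_qty_s2", "_unit", "_step"))
  }))
  c(
    "reaction_id", "reaction_type", "reuse_cycle", "yield_pct",
    "nucleophile_step_code", "intramolecular", "split_label",
    paste0("c_", 1:9), role_cols
  )
}

.mandatory_columns <- c("reaction_id", "reaction_type", "reuse_cycle", "yield_pct")

#' Column-mapping dialect for flat reaction tables
#'
#' Maps canonical column names to the column names used in a particular file.
#' Unmapped canonical columns are looked up under their own names; canonical
#' columns absent from the file are filled with `NA` (except the mandatory
#' four: `reaction_id`, `reaction_type`, `reuse_cycle`, `yield_pct`).
#'
#' @param ... named character entries, `canonical = "file_column"`.
#' @return a named character vector of class `ptml_dialect`.
#' @examples
#' ptml_dialect(yield_pct = "Yld_pct_n", reuse_cycle = "n")
#' @export
ptml_dialect <- function(...) {
  map <- c(...)
  if (is.null(map)) map <- character()
  if (length(map) && (is.null(names(map)) || any(names(map) == ""))) {
    abort("all dialect entries must be named (canonical = \"file column\")")
  }
  unknown <- setdiff(names(map), reaction_columns())
  if (length(unknown)) {
    abort(paste0(
      "unknown canonical column(s) in dialect: ",
      paste(unknown, collapse = ", ")
    ))
  }
  structure(map, class = "ptml_dialect")
}

# Coerce a raw file tibble into canonical form; row-level yield check.
.canonicalize_records <- function(raw, dialect = ptml_dialect()) {
  cols <- reaction_columns()
  map <- setNames(cols, cols)
  map[names(dialect)] <- unname(dialect)
  missing_mand <- .mandatory_columns[!map[.mandatory_columns] %in% names(raw)]
  if (length(missing_mand)) {
    abort(paste0(
      "missing mandatory column(s): ",
      paste(map[missing_mand], collapse = ", ")
    ), class = "ptml_schema_error")
  }
  out <- tibble(.rows = nrow(raw))
  for (cc in cols) {
    src <- map[[cc]]
    out[[cc]] <- if (src %in% names(raw)) raw[[src]] else NA
  }
  # extra columns (smiles, provenance flags, ...) are carried through untouched
  extras <- setdiff(names(raw), unname(map[map %in% names(raw)]))
  for (e in extras) out[[e]] <- raw[[e]]

  if (!is.numeric(out$yield_pct)) {
    suppressWarnings(num <- as.numeric(out$yield_pct))
    bad <- which(!is.na(out$yield_pct) & is.na(num))
    if (length(bad)) {
      abort(paste0(
        "non-numeric yield_pct at row(s): ",
        paste(head(bad, 10), collapse = ", ")
      ), class = "ptml_row_error")
    }
    out$yield_pct <- num
  }
  out$reaction_id <- as.character(out$reaction_id)
  out$reuse_cycle <- as.integer(out$reuse_cycle)
  out$nucleophile_step_code <- as.integer(out$nucleophile_step_code)
  out$intramolecular <- as.logical(out$intramolecular)
  out$split_label <- ifelse(is.na(out$split_label), "unassigned",
                            as.character(out$split_label))
  for (r in .ptml_roles) {
    for (s in c("_qty_s1", "_qty_s2")) {
      out[[paste0(r, s)]] <- as.numeric(out[[paste0(r, s)]])
    }
    for (s in c("_id", "_unit", "_step")) {
      out[[paste0(r, s)]] <- as.character(out[[paste0(r, s)]])
    }
  }
  for (j in paste0("c_", 1:9)) out[[j]] <- as.character(out[[j]])
  out
}

#' Read a flat reaction dataset
#'
#' Reads a one-row-per-trial reaction table (CSV, TSV or XLSX decided by the
#' file extension), applies a column-mapping dialect, and returns canonical
#' records in file order. Optionally reads companion long-format descriptor and
#' variable tables.
#'
#' @param path path to the reaction table.
#' @param dialect a [ptml_dialect()] mapping canonical to file columns.
#' @param descriptors,variables optional paths to companion tables read with
#'   [read_descriptors()] / [read_variables()].
#' @return a list with elements `records` (tibble, one row per trial, in file
#'   order), `descriptors` and `variables` (tibbles or `NULL`).
#' @export
read_dataset <- function(path, dialect = ptml_dialect(),
                         descriptors = NULL, variables = NULL) {
  list(
    records = read_reactions(path, dialect),
    descriptors = if (!is.null(descriptors)) read_descriptors(descriptors),
    variables = if (!is.null(variables)) read_variables(variables)
  )
}

.read_table_any <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    "xlsx" = {
      if (!requireNamespace("readxl", quietly = TRUE)) {
        abort("reading xlsx requires the readxl package")
      }
      readxl::read_excel(path)
    },
    "tsv" = readr::read_tsv(path, show_col_types = FALSE, progress = FALSE),
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  )
  as_tibble(raw)
}

#' @rdname read_dataset
#' @export
read_reactions <- function(path, dialect = ptml_dialect()) {
  raw <- .read_table_any(path)
  if (ncol(raw) == 0 || nrow(raw) == 0 && ncol(raw) == 0) {
    abort("empty file: no header row", class = "ptml_schema_error")
  }
  .canonicalize_records(raw, dialect)
}

#' Read long-format descriptor / variable tables
#'
#' Descriptor tables hold one molecular descriptor value per
#' `(molecule_id, descriptor_id)` pair; variable tables hold one functional
#' condition variable per `(reaction_id, variable_id)` pair. Both carry a unit
#' string per entry. Duplicate keys are an error.
#'
#' @param path CSV/TSV/XLSX file with columns `molecule_id`, `descriptor_id`,
#'   `value`, `unit` (descriptors) or `reaction_id`, `variable_id`, `value`,
#'   `unit` (variables).
#' @return a tibble in file order.
#' @export
read_descriptors <- function(path) {
  tab <- .read_table_any(path)
  .check_long_table(tab, c("molecule_id", "descriptor_id", "value"))
}

#' @rdname read_descriptors
#' @export
read_variables <- function(path) {
  tab <- .read_table_any(path)
  .check_long_table(tab, c("reaction_id", "variable_id", "value"))
}

.check_long_table <- function(tab, keys) {
  missing <- setdiff(keys, names(tab))
  if (length(missing)) {
    abort(paste0("missing mandatory column(s): ", paste(missing, collapse = ", ")),
          class = "ptml_schema_error")
  }
  if (!"unit" %in% names(tab)) tab$unit <- NA_character_
  dup <- duplicated(tab[keys[1:2]])
  if (any(dup)) {
    abort(paste0("duplicate keys at row(s): ",
                 paste(head(which(dup), 10), collapse = ", ")),
          class = "ptml_schema_error")
  }
  tab$value <- as.numeric(tab$value)
  for (k in keys[1:2]) tab[[k]] <- as.character(tab[[k]])
  as_tibble(tab[c(keys, "unit")])
}

# ---------------------------------------------------------------------------
# SURF (Simple User-Friendly Reaction Format), frozen dialect
# ---------------------------------------------------------------------------

#' Read and write reactions in the SURF exchange format
#'
#' SURF stores one reaction per line with role-tagged components. The exact
#' column vocabulary is not standardized, so this package freezes its own
#' tab-separated dialect: a header line followed by one record per line with
#' the canonical columns of [reaction_columns()] in order. Empty cells are
#' missing values. `write_surf()` followed by `read_surf()` is the identity on
#' canonical fields, and a second `write_surf()` reproduces the file byte for
#' byte.
#'
#' @param path file path.
#' @param records canonical reaction records; every record must carry a
#'   catalyst role (`catalyst_id`).
#' @return `read_surf()` returns a records tibble; `write_surf()` returns
#'   `path` invisibly.
#' @export
read_surf <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path)
  if (length(lines) < 1) abort("empty SURF file", class = "ptml_parse_error")
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (!identical(header, reaction_columns())) {
    abort("SURF header does not match the frozen dialect",
          class = "ptml_parse_error")
  }
  body <- lines[-1]
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- vapply(fields, length, integer(1))
  bad <- which(nf != length(header))
  if (length(bad)) {
    abort(paste0("malformed SURF record(s) at index: ",
                 paste(head(bad, 10), collapse = ", ")),
          class = "ptml_parse_error")
  }
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  out <- .canonicalize_records(raw)
  out$intramolecular <- out$intramolecular
  out
}

#' @rdname read_surf
#' @export
write_surf <- function(records, path) {
  no_cat <- is.na(records$catalyst_id) | records$catalyst_id == ""
  if (any(no_cat)) {
    abort(paste0("record(s) lacking a catalyst role at row(s): ",
                 paste(head(which(no_cat), 10), collapse = ", ")),
          class = "ptml_validation_error")
  }
  out <- records[reaction_columns()]
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Validation report
# ---------------------------------------------------------------------------

#' Validate a reaction dataset
#'
#' Report-only checks; the inputs are never modified. Rules:
#' `yield_range` (yield outside `[0,100]`), `unknown_reaction_type`,
#' `type_label_mismatch` (`c_8` disagrees with `reaction_type`),
#' `step_code_range` (`nucleophile_step_code` outside `{0,1,2,3}`),
#' `contradictory_step` (intramolecular but a nucleophile step tag present),
#' `dangling_molecule` (a role molecule absent from the descriptor table),
#' `missing_quantity` (role present without any quantity),
#' `missing_unit` (quantity present without a unit).
#'
#' @param records canonical records.
#' @param descriptors optional descriptor table to check molecule references.
#' @param variables optional variable table (reaction ids are cross-checked).
#' @return a tibble with columns `rule`, `row`, `reaction_id`, `detail`;
#'   zero rows when the dataset is clean.
#' @export
validate_dataset <- function(records, descriptors = NULL, variables = NULL) {
  findings <- list()
  add <- function(rule, rows, detail) {
    if (length(rows)) {
      findings[[length(findings) + 1]] <<- tibble(
        rule = rule, row = rows,
        reaction_id = records$reaction_id[rows], detail = detail
      )
    }
  }
  y <- records$yield_pct
  add("yield_range", which(!is.na(y) & (y < 0 | y > 100)), "yield outside [0,100]")
  add("unknown_reaction_type",
      which(!is.na(records$reaction_type) &
              !records$reaction_type %in% .ptml_reaction_types),
      "reaction_type not in the canonical vocabulary")
  add("type_label_mismatch",
      which(!is.na(records$c_8) & records$c_8 != records$reaction_type),
      "condition label c_8 disagrees with reaction_type")
  ns <- records$nucleophile_step_code
  add("step_code_range", which(!is.na(ns) & !ns %in% 0:3),
      "nucleophile_step_code outside {0,1,2,3}")
  intra <- !is.na(records$intramolecular) & records$intramolecular
  tag <- records$nucleophile_step
  tagged <- !is.na(tag) & !tag %in% c("", "n/a")
  add("contradictory_step", which(intra & tagged),
      "intramolecular reaction carries a nucleophile step tag")
  for (r in .ptml_roles) {
    id <- records[[paste0(r, "_id")]]
    q1 <- records[[paste0(r, "_qty_s1")]]
    q2 <- records[[paste0(r, "_qty_s2")]]
    un <- records[[paste0(r, "_unit")]]
    has_id <- !is.na(id) & id != ""
    has_qty <- !is.na(q1) | !is.na(q2)
    add("missing_quantity", which(has_id & !has_qty),
        paste0("role ", r, " has no quantity"))
    add("missing_unit", which(has_qty & (is.na(un) | un == "")),
        paste0("role ", r, " quantity lacks a unit"))
    if (!is.null(descriptors)) {
      known <- unique(descriptors$molecule_id)
      add("dangling_molecule", which(has_id & !id %in% known),
          paste0("role ", r, " molecule absent from descriptor table"))
    }
  }
  if (!is.null(variables)) {
    orphan <- setdiff(unique(variables$reaction_id), records$reaction_id)
    if (length(orphan)) {
      findings[[length(findings) + 1]] <- tibble(
        rule = "orphan_variable_row", row = NA_integer_,
        reaction_id = orphan,
        detail = "variable table reaction_id absent from records"
      )
    }
  }
  if (!length(findings)) {
    return(tibble(rule = character(), row = integer(),
                  reaction_id = character(), detail = character()))
  }
  bind_rows(findings)
}
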
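#' Group-mean imputation of missing numeric fields
#'
#' Catalyst-amount fields in curated recyclability datasets are often
#' unreported. Each missing value is filled with the mean of the non-missing
#' values among trials sharing the same metal (`c_4`), support (`c_2`),
#' synthesis procedure (`c_5`) and reuse cycle. When that exact group has no
#' observed value, the key is relaxed along a fallback ladder, dropping the
#' most specific component first: reuse cycle, then synthesis procedure, then
#' support, and finally the global mean.
#'
#' Filled cells are flagged in a companion logical column
#' `<target_field>_imputed`, mirroring the provenance distinction between
#' literature-extracted and computed values, so downstream stages can exclude
#' them.
#'
#' @param records canonical reaction records.
#' @param target_field name of the numeric column to fill
#'   (e.g. `"catalyst_qty_s1"`).
#' @param key character vector of grouping columns, most general first and
#'   most specific last; components are dropped from the right.
#' @return a list with `records` (filled) and `log`, a tibble with one row per
#'   filled cell: `row`, `reaction_id`, `field`, `value`, `ladder_level`
#'   (0 = exact key, increasing as components are dropped; the last level is
#'   the global mean).
#' @export
impute_group_mean <- function(records, target_field = "catalyst_qty_s1",
                              key = c("c_2", "c_5", "c_4", "reuse_cycle")) {
  x <- records[[target_field]]
  if (is.null(x)) abort(paste0("no such field: ", target_field))
  if (!is.numeric(x)) abort(paste0(target_field, " is not numeric"))
  miss <- which(is.na(x))
  log <- tibble(row = integer(), reaction_id = character(),
                field = character(), value = double(), ladder_level = integer())
  flag_col <- paste0(target_field, "_imputed")
  if (!flag_col %in% names(records)) records[[flag_col]] <- FALSE
  records[[flag_col]][is.na(records[[flag_col]])] <- FALSE
  if (!length(miss)) return(list(records = records, log = log))
  if (all(is.na(x))) {
    abort(paste0("no non-missing values of ", target_field,
                 " at any ladder level; rows: ",
                 paste(head(miss, 10), collapse = ", ")),
          class = "ptml_imputation_error")
  }
  # ladder level L keeps the first (length(key) - L) key components;
  # level length(key) is the global mean
  keymat <- records[key]
  obs <- !is.na(x)
  fill <- rep(NA_real_, length(miss))
  level <- rep(NA_integer_, length(miss))
  for (L in 0:length(key)) {
    todo <- which(is.na(fill))
    if (!length(todo)) break
    keep <- key[seq_len(length(key) - L)]
    if (length(keep)) {
      gk <- do.call(paste, c(lapply(keymat[keep], function(v) trimws(as.character(v))),
                             sep = "\r"))
      means <- tapply(x[obs], gk[obs], mean)
      got <- means[gk[miss[todo]]]
    } else {
      got <- rep(mean(x[obs]), length(todo))
    }
    hit <- !is.na(got)
    fill[todo[hit]] <- unname(got[hit])
    level[todo[hit]] <- L
  }
  records[[target_field]][miss] <- fill
  records[[flag_col]][miss] <- TRUE
  list(
    records = records,
    log = tibble(row = miss, reaction_id = records$reaction_id[miss],
                 field = target_field, value = fill, ladder_level = level)
  )
}

#' Quantity-weight a descriptor or variable value
#'
#' Molecular descriptors and condition variables become more informative when
#' scaled by the amount of reagent actually used, so selected values are
#' multiplied by their quantities. For a reagent added in both reaction steps
#' the total quantity (step 1 + step 2) is used. The unit of the result is the
#' product unit, e.g. `pm` x `ug` -> `pm·ug`.
#'
#' @param value descriptor/variable value (vectorized).
#' @param quantity quantity for single-step reagents; ignored when `steps` is
#'   given. Must be `>= 0`.
#' @param steps optional named numeric vector/list of per-step quantities
#'   (names `"1"`, `"2"`); their sum is used.
#' @param unit,quantity_unit optional unit strings; when both given the result
#'   carries a `unit` attribute `"<unit>·<quantity_unit>"`.
#' @return `value * total_quantity`.
#' @examples
#' quantity_weight(3, 2)                  # 6
#' quantity_weight(1.5, steps = c("1" = 2, "2" = 1))  # 4.5
#' @export
quantity_weight <- function(value, quantity = NULL, steps = NULL,
                            unit = NULL, quantity_unit = NULL) {
  if (!is.null(steps)) {
    q <- sum(unlist(steps))
  } else {
    q <- quantity
  }
  if (is.null(q)) abort("either quantity or steps must be given")
  if (any(q < 0, na.rm = TRUE)) {
    abort("negative quantity", class = "ptml_domain_error")
  }
  out <- value * q
  if (!is.null(unit) && !is.null(quantity_unit)) {
    attr(out, "unit") <- paste0(unit, "·", quantity_unit)
  }
  out
}

#' Encode the nucleophile addition step
#'
#' Two-step reactions add the nucleophile at different points, which matters
#' for the outcome; the convention is an integer code: 0 for intramolecular
#' reactions (no separate nucleophile), 1 for addition in step 1, 2 for step
#' 2, and 3 for addition in both steps.
#'
#' @param records canonical records; uses `intramolecular` and the
#'   nucleophile role's step tag `nucleophile_step` (`"1"`, `"2"`, `"both"`,
#'   `"n/a"`).
#' @return an integer vector of codes in `{0,1,2,3}`. A record that is both
#'   intramolecular and carries a nucleophile step tag is contradictory and
#'   raises a validation error.
#' @export
encode_nucleophile_step <- function(records) {
  intra <- !is.na(records$intramolecular) & records$intramolecular
  tag <- records$nucleophile_step
  if (is.numeric(tag)) tag <- as.character(tag)
  tag <- ifelse(is.na(tag) | tag %in% c("", "n/a"), NA_character_, tag)
  bad <- which(intra & !is.na(tag) & tag != "0")
  if (length(bad)) {
    abort(paste0("contradictory step tags (intramolecular + nucleophile step) ",
                 "at row(s): ", paste(head(bad, 10), collapse = ", ")),
          class = "ptml_validation_error")
  }
  code <- dplyr::case_when(
    intra ~ 0L,
    tag %in% c("1") ~ 1L,
    tag %in% c("2") ~ 2L,
    tag %in% c("3", "both") ~ 3L,
    TRUE ~ NA_integer_
  )
  unknown <- which(!intra & is.na(code) & !is.na(tag))
  if (length(unknown)) {
    abort(paste0("unrecognized nucleophile step tag at row(s): ",
                 paste(head(unknown, 10), collapse = ", ")),
          class = "ptml_validation_error")
  }
  code
}

#' Build the per-reaction value table
#'
#' Resolves every variable `V<k>` and every descriptor `D<k>` to one numeric
#' value per reaction, the form consumed by [assemble_features()]. Variables
#' pivot directly from the long variable table. Descriptors belong to
#' molecules, so each descriptor id is routed through a role map (which of the
#' reaction's components carries it). Quantity weighting of a descriptor can
#' happen in either of two places: set `weight_quantities = TRUE` to multiply
#' each descriptor by its role's total quantity here (via the
#' [quantity_weight()] rule), or leave descriptors raw (the default) and put
#' the product into the recipe expression — the published recipe does the
#' latter, pairing each descriptor explicitly with its amount variable
#' (`D2 * V2`, `D6 * V8`, `D15 * (V10 + V35)`). Do not do both, or the
#' quantity is counted twice.
#'
#' @param records canonical records.
#' @param descriptors long descriptor table (`molecule_id`, `descriptor_id`,
#'   `value`, `unit`).
#' @param variables long variable table (`reaction_id`, `variable_id`,
#'   `value`, `unit`).
#' @param role_map named character vector, descriptor id -> role. Defaults to
#'   the package's frozen assignment for the published-recipe descriptors:
#'   D2 -> catalyst, D6 -> nucleophile, D15 -> base.
#' @param weight_quantities logical; multiply descriptor values by the role's
#'   total quantity (default `FALSE`; see above).
#' @return a tibble, one row per reaction: `reaction_id` plus one numeric
#'   column per variable and per mapped descriptor.
#' @export
build_value_table <- function(records, descriptors = NULL, variables = NULL,
                              role_map = c(D2 = "catalyst", D6 = "nucleophile",
                                           D15 = "base"),
                              weight_quantities = FALSE) {
  out <- tibble(reaction_id = records$reaction_id)
  if (!is.null(variables)) {
    wide <- tidyr::pivot_wider(variables[c("reaction_id", "variable_id", "value")],
                               names_from = "variable_id", values_from = "value")
    out <- left_join(out, wide, by = "reaction_id")
  }
  if (!is.null(descriptors)) {
    for (dk in names(role_map)) {
      role <- role_map[[dk]]
      dvals <- descriptors[descriptors$descriptor_id == dk, ]
      lookup <- setNames(dvals$value, dvals$molecule_id)
      mol <- records[[paste0(role, "_id")]]
      v <- unname(lookup[mol])
      if (weight_quantities) {
        q1 <- records[[paste0(role, "_qty_s1")]]
        q2 <- records[[paste0(role, "_qty_s2")]]
        qty <- ifelse(is.na(q1), 0, q1) + ifelse(is.na(q2), 0, q2)
        qty[is.na(q1) & is.na(q2)] <- NA_real_
        v <- v * qty
      }
      out[[dk]] <- v
    }
  }
  out
}
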
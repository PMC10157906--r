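#' Normalize raw drug names to canonical tokens
#'
#' Canonicalization is deliberately simple and deterministic: case-fold,
#' trim surrounding whitespace, collapse internal runs of whitespace, then
#' apply the synonym dictionary.  Duplicates collapse because the result is
#' a set.  There is no fuzzy matching: two drugs are the same drug exactly
#' when their canonical tokens are equal.
#'
#' @param raw_names character vector of raw drug names.
#' @param synonyms a synonym map built by [synonym_map()] or
#'   [read_synonyms()], or `NULL` for no synonym substitution.
#' @return character vector: the sorted set of canonical names.
#' @examples
#' normalize_drugs(c("Xianlingpi", "Epimedium"),
#'                 synonym_map(c(Xianlingpi = "Epimedium")))
#' @export
normalize_drugs <- function(raw_names, synonyms = NULL) {
  if (length(raw_names) == 0L) {
    stop("invalid prescription: no drug names supplied", call. = FALSE)
  }
  x <- canonical_token(as.character(raw_names))
  x <- x[nzchar(x)]
  if (!is.null(synonyms)) {
    hit <- match(x, names(synonyms))
    x[!is.na(hit)] <- unname(synonyms[hit[!is.na(hit)]])
  }
  x <- sort(unique(x))
  if (length(x) == 0L) {
    stop("invalid prescription: all drug names normalize to empty",
         call. = FALSE)
  }
  x
}

canonical_token <- function(x) {
  x <- tolower(trimws(x))
  gsub("[[:space:]]+", " ", x)
}

#' Build a synonym map from raw name to canonical drug name
#'
#' Both sides are canonicalized (case-fold, trim), and the map is made
#' idempotent: applying it to one of its own canonical names returns that
#' name unchanged.
#'
#' @param entries named character vector, `raw = canonical`.
#' @return named character vector of class `synonym_map`.
#' @export
synonym_map <- function(entries = character()) {
  if (length(entries) == 0L) {
    return(structure(character(), class = "synonym_map"))
  }
  if (is.null(names(entries)) || any(!nzchar(names(entries)))) {
    stop("synonym entries must be a named vector (raw = canonical)",
         call. = FALSE)
  }
  raw <- canonical_token(names(entries))
  canon <- canonical_token(as.character(entries))
  keep <- !duplicated(raw) & raw != canon
  m <- structure(canon[keep], names = raw[keep], class = "synonym_map")
  # resolve chains (a -> b, b -> c) so one application suffices
  repeat {
    hit <- match(unname(m), names(m))
    if (all(is.na(hit))) break
    m[!is.na(hit)] <- unname(m)[hit[!is.na(hit)]]
    # guard against cycles: a cycle would loop forever, drop its entries
    if (any(names(m) == unname(m))) {
      m <- m[names(m) != unname(m)]
      class(m) <- "synonym_map"
    }
  }
  m
}

#' Construct a standard formula with graded drug levels
#'
#' A standard (classical) prescription whose drugs are graded into the four
#' importance levels of the chief/deputy/assistant/envoy convention
#' (C1-C4).  The full composition set (the C5 role) contains every drug of
#' the formula, including any drug not assigned to a level.
#'
#' @param name formula name (unique within a formulary).
#' @param c1,c2,c3,c4 character vectors of drug names per level; may be
#'   empty.
#' @param extra drugs belonging to the formula but not graded into a level.
#' @param source free-text provenance.
#' @param synonyms optional synonym map applied to every drug name.
#' @return object of class `standard_formula` with fields `name`, `source`,
#'   `levels` (list C1..C4) and `full` (the C5 set).
#' @export
standard_formula <- function(name, c1 = character(), c2 = character(),
                             c3 = character(), c4 = character(),
                             extra = character(), source = "",
                             synonyms = NULL) {
  norm <- function(v) {
    if (length(v) == 0L) character() else normalize_drugs(v, synonyms)
  }
  levels <- list(C1 = norm(c1), C2 = norm(c2), C3 = norm(c3), C4 = norm(c4))
  full <- sort(unique(c(unlist(levels, use.names = FALSE), norm(extra))))
  f <- structure(
    list(name = as.character(name)[1L], source = as.character(source)[1L],
         levels = levels, full = full),
    class = "standard_formula"
  )
  validate_formula(f)
  f
}

validate_formula <- function(f) {
  lv <- unlist(f$levels, use.names = FALSE)
  if (anyDuplicated(lv)) {
    dup <- unique(lv[duplicated(lv)])
    stop(sprintf("formula '%s': drug(s) %s assigned to more than one level",
                 f$name, paste(sQuote(dup), collapse = ", ")),
         call. = FALSE)
  }
  if (!all(lv %in% f$full)) {
    stop(sprintf("formula '%s': level drugs missing from the full set",
                 f$name), call. = FALSE)
  }
  if (length(f$full) == 0L) {
    stop(sprintf("formula '%s': empty composition", f$name), call. = FALSE)
  }
  invisible(f)
}

#' Construct a formulary (collection of standard formulas)
#'
#' @param formulas list of [standard_formula()] objects.
#' @return object of class `formulary`; formulas are keyed by name.
#' @export
formulary <- function(formulas = list()) {
  stopifnot(is.list(formulas))
  for (f in formulas) {
    if (!inherits(f, "standard_formula")) {
      stop("all elements must be standard_formula objects", call. = FALSE)
    }
    validate_formula(f)
  }
  nm <- vapply(formulas, `[[`, "", "name")
  if (anyDuplicated(nm)) {
    stop(sprintf("duplicate formula name(s): %s",
                 paste(sQuote(unique(nm[duplicated(nm)])), collapse = ", ")),
         call. = FALSE)
  }
  names(formulas) <- nm
  structure(list(formulas = formulas), class = "formulary")
}

#' @export
length.formulary <- function(x) length(x$formulas)

#' @export
print.formulary <- function(x, ...) {
  sizes <- vapply(x$formulas, function(f) length(f$full), 0L)
  cat(sprintf("<formulary> %d standard formula(s), %d distinct drugs\n",
              length(x), length(unique(unlist(lapply(x$formulas,
                                                     `[[`, "full"))))))
  if (length(x)) {
    cat(sprintf("  composition size: median %g [%g, %g]\n",
                stats::median(sizes), min(sizes), max(sizes)))
  }
  invisible(x)
}

#' Construct a clinical prescription
#'
#' An identified drug-name set, optionally carrying the manually assigned
#' names of the standard formulas it contains (used for training and
#' evaluation).  Prescriptions never carry level information; levels come
#' from the formulary alone.
#'
#' @param id sample identifier.
#' @param drugs character vector of drug names (normalized, deduplicated).
#' @param labels optional character vector of formula names, or `NULL` for
#'   an unlabelled prescription.
#' @param synonyms optional synonym map.
#' @return object of class `prescription`.
#' @export
prescription <- function(id, drugs, labels = NULL, synonyms = NULL) {
  structure(
    list(id = as.character(id)[1L],
         drugs = normalize_drugs(drugs, synonyms),
         labels = if (is.null(labels)) NULL else
           sort(unique(as.character(labels)))),
    class = "prescription"
  )
}

#' @export
print.prescription <- function(x, ...) {
  cat(sprintf("<prescription> %s: %d drug(s)%s\n", x$id, length(x$drugs),
              if (is.null(x$labels)) "" else
                sprintf(", labels: %s", paste(x$labels, collapse = "; "))))
  invisible(x)
}

# ---- I/O ------------------------------------------------------------------

#' Read / write a formulary as JSON
#'
#' The on-disk layout is
#' `{"formulas":[{"name":..,"source":..,"levels":{"C1":[..],..},"full":[..]}]}`.
#' Level disjointness and full-set containment are validated on load;
#' violations raise an error naming the offending formula.
#'
#' @param path file path.
#' @return `read_formulary()` returns a [formulary()].
#' @export
read_formulary <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(doc$formulas)) {
    stop("formulary file has no 'formulas' field: ", path, call. = FALSE)
  }
  formulas <- lapply(doc$formulas, function(rec) {
    if (is.null(rec$name) || !nzchar(rec$name)) {
      stop("formulary record without a name in ", path, call. = FALSE)
    }
    lv <- rec$levels
    ch <- function(v) as.character(unlist(v))
    full <- ch(rec$full)
    assigned <- ch(c(lv$C1, lv$C2, lv$C3, lv$C4))
    standard_formula(rec$name,
                     c1 = ch(lv$C1), c2 = ch(lv$C2),
                     c3 = ch(lv$C3), c4 = ch(lv$C4),
                     extra = setdiff(full, assigned),
                     source = if (is.null(rec$source)) "" else rec$source)
  })
  formulary(formulas)
}

#' @rdname read_formulary
#' @param x a formulary.
#' @export
write_formulary <- function(x, path) {
  stopifnot(inherits(x, "formulary"))
  recs <- lapply(unname(x$formulas), function(f) {
    list(name = f$name, source = f$source,
         levels = lapply(f$levels, as.list),
         full = as.list(f$full))
  })
  jsonlite::write_json(list(formulas = recs), path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' Read / write clinical prescriptions
#'
#' CSV dialect: columns `id`, `drugs` (pipe-delimited), and optionally
#' `labels` (semicolon-delimited).  JSONL dialect (one object per line):
#' fields `id`, `drugs` (array), `labels` (array, optional).  The format is
#' chosen by file extension (`.jsonl` / `.ndjson` vs anything else = CSV).
#'
#' @param path file path.
#' @param synonyms optional synonym map applied to drug names.
#' @return list of [prescription()] objects.
#' @export
read_prescriptions <- function(path, synonyms = NULL) {
  if (grepl("\\.(jsonl|ndjson)$", path, ignore.case = TRUE)) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    recs <- lapply(seq_along(lines), function(i) {
      rec <- jsonlite::fromJSON(lines[[i]], simplifyVector = TRUE)
      if (is.null(rec$id) || !nzchar(rec$id)) {
        stop(sprintf("line %d: missing id", i), call. = FALSE)
      }
      if (length(rec$drugs) == 0L) {
        stop(sprintf("line %d (id %s): empty drug list", i, rec$id),
             call. = FALSE)
      }
      prescription(rec$id, rec$drugs,
                   labels = rec$labels, synonyms = synonyms)
    })
    return(recs)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (!all(c("id", "drugs") %in% names(df))) {
    stop("prescription CSV needs columns 'id' and 'drugs': ", path,
         call. = FALSE)
  }
  has_labels <- "labels" %in% names(df)
  lapply(seq_len(nrow(df)), function(i) {
    id <- trimws(df$id[i])
    if (!nzchar(id)) stop(sprintf("row %d: missing id", i), call. = FALSE)
    drugs <- strsplit(df$drugs[i], "|", fixed = TRUE)[[1L]]
    drugs <- drugs[nzchar(trimws(drugs))]
    if (length(drugs) == 0L) {
      stop(sprintf("row %d (id %s): empty drug list", i, id), call. = FALSE)
    }
    labels <- NULL
    if (has_labels && nzchar(trimws(df$labels[i]))) {
      labels <- trimws(strsplit(df$labels[i], ";", fixed = TRUE)[[1L]])
      labels <- labels[nzchar(labels)]
    }
    prescription(id, drugs, labels = labels, synonyms = synonyms)
  })
}

#' @rdname read_prescriptions
#' @param x list of prescriptions.
#' @export
write_prescriptions <- function(x, path) {
  df <- data.frame(
    id = vapply(x, `[[`, "", "id"),
    drugs = vapply(x, function(p) paste(p$drugs, collapse = "|"), ""),
    labels = vapply(x, function(p)
      if (is.null(p$labels)) "" else paste(p$labels, collapse = ";"), ""),
    stringsAsFactors = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a two-column synonym CSV (`raw,canonical`)
#'
#' @param path file path.
#' @return a [synonym_map()].
#' @export
read_synonyms <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (ncol(df) < 2L) {
    stop("synonym CSV needs two columns (raw, canonical): ", path,
         call. = FALSE)
  }
  synonym_map(structure(df[[2L]], names = df[[1L]]))
}
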
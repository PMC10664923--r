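# Vocabulary handling: ICD-10 hierarchy, CCSR category maps, treatment codes,
# level remapping and category exclusion.

#' Normalize a medical event code
#'
#' Strips dots and whitespace and uppercases, so that the `"C67.2"` and
#' `"C672"` spellings found in real extracts collapse to one token. Treatment
#' codes (prefix `"TX:"`) keep their colon.
#'
#' @param code character vector of raw codes.
#' @return character vector of normalized codes.
#' @export
normalize_code <- function(code) {
  toupper(gsub("[.[:space:]]", "", as.character(code)))
}

.new_vocab <- function(codes_dt, mode, ccsr_map = NULL) {
  data.table::setkey(codes_dt, code)
  v <- list(
    codes = codes_dt,
    mode = mode,
    ccsr_map = ccsr_map,
    excluded = character(0),
    whitelist = character(0),
    counters = new.env(parent = emptyenv())
  )
  v$counters$unmapped <- 0L
  # fast lookup vectors
  v$parent <- stats::setNames(codes_dt$parent, codes_dt$code)
  v$depth <- stats::setNames(codes_dt$depth, codes_dt$code)
  v$kind <- stats::setNames(codes_dt$kind, codes_dt$code)
  v$name <- stats::setNames(codes_dt$name, codes_dt$code)
  class(v) <- "traj_vocab"
  v
}

#' @export
print.traj_vocab <- function(x, ...) {
  cat(sprintf(
    "<traj_vocab> mode=%s, %d codes (%d treatment), %d exclusion roots\n",
    x$mode, nrow(x$codes), sum(x$codes$kind == "treatment"), length(x$excluded)
  ))
  invisible(x)
}

.validate_hierarchy <- function(dt, source) {
  if (anyDuplicated(dt$code)) {
    .fail("duplicate code(s) in hierarchy '", source, "': ",
          paste(unique(dt$code[duplicated(dt$code)]), collapse = ", "))
  }
  known <- dt$code
  orphan <- !is.na(dt$parent) & !(dt$parent %in% known)
  if (any(orphan)) {
    .fail("orphan code(s) in hierarchy '", source, "' (parent missing): ",
          paste(sprintf("%s (parent %s)", dt$code[orphan], dt$parent[orphan]), collapse = ", "))
  }
  # depth = path length to a root; also serves as the cycle guard (<= 6 steps)
  pmap <- stats::setNames(dt$parent, dt$code)
  depth <- integer(nrow(dt))
  for (i in seq_len(nrow(dt))) {
    d <- 0L
    p <- pmap[[dt$code[i]]]
    while (!is.na(p)) {
      d <- d + 1L
      if (d > 6L) .fail("parent chain longer than 6 steps (cycle?) at code '", dt$code[i], "'")
      p <- pmap[[p]]
    }
    depth[i] <- d
  }
  dt$depth <- depth
  dt
}

#' Load an ICD-10 hierarchy into a vocabulary
#'
#' Two hierarchy dialects are supported and auto-detected: a ClaML-style XML
#' file (`Class` elements carrying a `code` attribute, an optional
#' `SuperClass` child referencing the parent code, and a preferred-label
#' `Rubric`), and a flat tab-separated table with columns
#' `code`, `parent`, `depth`, `name` (empty parent marks a chapter/root).
#' Codes are normalized with [normalize_code()]; depths are recomputed from
#' the parent chain with chapters at depth 0, blocks at 1, three-character
#' categories at 2 and subcategories at 3.
#'
#' @param source path to the hierarchy file.
#' @return a `traj_vocab` object in `"icd-hierarchy"` mode.
#' @seealso [load_ccsr_map()], [map_to_level()], [set_exclusions()]
#' @export
load_icd_hierarchy <- function(source) {
  if (!file.exists(source)) .fail("hierarchy file not found: ", source)
  head_bytes <- readChar(source, nchars = 256L, useBytes = TRUE)
  if (!nzchar(gsub("[[:space:]]", "", head_bytes))) .fail("empty hierarchy file: ", source)
  is_xml <- grepl("^\\s*<", head_bytes)
  dt <- if (is_xml) .read_claml(source) else .read_flat_hierarchy(source)
  if (nrow(dt) == 0L) .fail("hierarchy file contains no codes: ", source)
  dt <- .validate_hierarchy(dt, source)
  .new_vocab(dt, mode = "icd-hierarchy")
}

.read_claml <- function(source) {
  doc <- tryCatch(xml2::read_xml(source), error = function(e) {
    .fail("cannot parse XML hierarchy '", source, "': ", conditionMessage(e))
  })
  classes <- xml2::xml_find_all(doc, ".//Class")
  if (length(classes) == 0L) .fail("no Class elements in XML hierarchy: ", source)
  code <- xml2::xml_attr(classes, "code")
  bad <- which(is.na(code) | !nzchar(code))
  if (length(bad)) .fail("Class element #", bad[1], " in '", source, "' has no code attribute")
  parent <- vapply(classes, function(cl) {
    sup <- xml2::xml_find_first(cl, "./SuperClass")
    if (inherits(sup, "xml_missing")) NA_character_ else xml2::xml_attr(sup, "code")
  }, character(1))
  name <- vapply(classes, function(cl) {
    lab <- xml2::xml_find_first(cl, "./Rubric[@kind='preferred']/Label")
    if (inherits(lab, "xml_missing")) lab <- xml2::xml_find_first(cl, ".//Label")
    if (inherits(lab, "xml_missing")) NA_character_ else xml2::xml_text(lab)
  }, character(1))
  data.table::data.table(
    code = normalize_code(code),
    parent = ifelse(is.na(parent), NA_character_, normalize_code(parent)),
    depth = NA_integer_,
    name = ifelse(is.na(name), code, name),
    kind = "diagnosis"
  )
}

.read_flat_hierarchy <- function(source) {
  dt <- tryCatch(
    data.table::fread(source, sep = "\t", header = TRUE, colClasses = "character", na.strings = ""),
    error = function(e) .fail("cannot parse flat hierarchy '", source, "': ", conditionMessage(e))
  )
  need <- c("code", "parent", "name")
  miss <- setdiff(need, tolower(names(dt)))
  if (length(miss)) .fail("flat hierarchy '", source, "' lacks column(s): ", paste(miss, collapse = ", "))
  data.table::setnames(dt, tolower(names(dt)))
  data.table::data.table(
    code = normalize_code(dt$code),
    parent = ifelse(is.na(dt$parent) | dt$parent == "", NA_character_, normalize_code(dt$parent)),
    depth = NA_integer_,
    name = ifelse(is.na(dt$name), dt$code, dt$name),
    kind = "diagnosis"
  )
}

#' Load a CCSR category map as a vocabulary
#'
#' Reads a CSV with header `ICD10,CCSR_CATEGORY,CCSR_DESCRIPTION` mapping each
#' ICD-10 code to exactly one Clinical Classifications Software Refined
#' category. The resulting vocabulary's analysis-level codes are the CCSR
#' categories themselves; [map_to_level()] then performs a direct table
#' lookup regardless of the requested level. ICD codes met at mapping time
#' that have no CCSR entry are counted (see [vocab_unmapped_count()]).
#'
#' @param source path to the CSV file.
#' @return a `traj_vocab` object in `"ccsr"` mode.
#' @export
load_ccsr_map <- function(source) {
  if (!file.exists(source)) .fail("CCSR file not found: ", source)
  dt <- tryCatch(
    data.table::fread(source, header = TRUE, colClasses = "character", na.strings = ""),
    error = function(e) .fail("cannot parse CCSR table '", source, "': ", conditionMessage(e))
  )
  data.table::setnames(dt, toupper(names(dt)))
  need <- c("ICD10", "CCSR_CATEGORY", "CCSR_DESCRIPTION")
  miss <- setdiff(need, names(dt))
  if (length(miss)) .fail("CCSR table '", source, "' lacks column(s): ", paste(miss, collapse = ", "))
  if (nrow(dt) == 0L) .fail("empty CCSR table: ", source)
  icd <- normalize_code(dt$ICD10)
  cat_ <- normalize_code(dt$CCSR_CATEGORY)
  # identical duplicate rows are tolerated; conflicting ones are not
  u <- !duplicated(paste(icd, cat_, sep = "\r"))
  icd_u <- icd[u]; cat_u <- cat_[u]
  dup <- unique(icd_u[duplicated(icd_u)])
  if (length(dup)) {
    .fail("conflicting CCSR mappings for ICD code(s): ", paste(dup, collapse = ", "))
  }
  cats <- !duplicated(cat_)
  codes_dt <- data.table::data.table(
    code = cat_[cats],
    parent = NA_character_,
    depth = 0L,
    name = dt$CCSR_DESCRIPTION[cats],
    kind = "diagnosis"
  )
  .new_vocab(codes_dt, mode = "ccsr", ccsr_map = stats::setNames(cat_u, icd_u))
}

#' Build a flat vocabulary from a plain code list
#'
#' For inputs that carry no hierarchy (synthetic cohorts, opaque local coding
#' systems) every code is its own analysis-level unit: no parents, depth 0,
#' level mapping is the identity.
#'
#' @param codes character vector of codes.
#' @param names optional human-readable labels (defaults to the codes).
#' @param kinds `"diagnosis"` or `"treatment"` per code (recycled).
#' @return a `traj_vocab` object in `"flat"` mode.
#' @export
vocabulary_from_codes <- function(codes, names = codes, kinds = "diagnosis") {
  codes <- normalize_code(codes)
  if (anyDuplicated(codes)) .fail("duplicate codes in vocabulary")
  dt <- data.table::data.table(
    code = codes, parent = NA_character_, depth = 0L,
    name = as.character(names), kind = rep_len(kinds, length(codes))
  )
  .new_vocab(dt, mode = "flat")
}

#' Register treatment codes in a vocabulary
#'
#' Treatment codes (e.g. `"TX:RADICAL_CYSTECTOMY"`) participate in the
#' analysis as ordinary timestamped events but sit outside the diagnosis
#' hierarchy: they have no parent and are never remapped by
#' [map_to_level()].
#'
#' @param vocab a `traj_vocab`.
#' @param codes character vector of treatment codes.
#' @param names optional labels.
#' @return the updated vocabulary.
#' @export
register_treatments <- function(vocab, codes, names = codes) {
  stopifnot(inherits(vocab, "traj_vocab"))
  codes <- normalize_code(codes)
  new <- !(codes %in% vocab$codes$code)
  if (!any(new)) return(vocab)
  add <- data.table::data.table(
    code = codes[new], parent = NA_character_, depth = 0L,
    name = as.character(names)[new], kind = "treatment"
  )
  .new_vocab(rbind(vocab$codes, add), mode = vocab$mode, ccsr_map = vocab$ccsr_map) |>
    set_exclusions(roots = vocab$excluded, whitelist = vocab$whitelist)
}

#' Configure category exclusions
#'
#' Excluding a code excludes its entire subtree: [is_excluded()] walks the
#' ancestor chain, so the exclusion set is closed under descendants by
#' construction. Whitelisted codes take precedence and are never excluded
#' (used e.g. to keep a personal-history anchor code while dropping the rest
#' of its chapter).
#'
#' @param vocab a `traj_vocab`.
#' @param roots character vector of codes/chapters to exclude (normalized).
#' @param whitelist character vector of codes exempted from exclusion.
#' @return the updated vocabulary.
#' @export
set_exclusions <- function(vocab, roots, whitelist = character(0)) {
  stopifnot(inherits(vocab, "traj_vocab"))
  vocab$excluded <- normalize_code(roots)
  vocab$whitelist <- normalize_code(whitelist)
  vocab
}

#' Load the default exclusion list shipped with the package
#'
#' The default removes the ICD-10 chapters for pregnancy/childbirth (XV),
#' perinatal conditions (XVI), external causes (XX) and
#' factors-influencing-health-status Z codes (XXI), while whitelisting the
#' personal-history-of-bladder-cancer codes used as cohort anchors. The list
#' lives in `inst/extdata/default_exclusions.tsv` and can be replaced.
#'
#' @param vocab a `traj_vocab`.
#' @param path optional path to an alternative exclusions TSV with columns
#'   `role` (`exclude`/`whitelist`) and `code`.
#' @return the updated vocabulary.
#' @export
apply_default_exclusions <- function(vocab, path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "default_exclusions.tsv", package = "trajmine")
  }
  dt <- data.table::fread(path, sep = "\t", header = TRUE, colClasses = "character")
  set_exclusions(vocab,
    roots = dt$code[dt$role == "exclude"],
    whitelist = dt$code[dt$role == "whitelist"]
  )
}

# ancestor chain of a (normalized, known) code, self first
.ancestry <- function(vocab, code) {
  out <- code
  p <- vocab$parent[[code]]
  n <- 0L
  while (!is.na(p)) {
    out <- c(out, p)
    n <- n + 1L
    if (n > 6L) break
    p <- if (p %in% names(vocab$parent)) vocab$parent[[p]] else NA_character_
  }
  out
}

#' Map a code to the analysis level
#'
#' In ICD-hierarchy mode, returns the ancestor of `code` at depth `level`
#' (chapter = 0, block = 1, three-character category = 2, subcategory = 3);
#' a code already at or above the requested level is returned unchanged. In
#' CCSR mode the mapped CCSR category is returned whatever the level. In flat
#' mode mapping is the identity. Treatment codes always bypass mapping.
#'
#' Unknown codes follow `policy`: `"drop-with-warning"` (default) returns
#' `NA` and increments the vocabulary's unmapped counter; `"error"` aborts.
#'
#' @param vocab a `traj_vocab`.
#' @param code character vector of codes (normalized internally).
#' @param level non-negative integer analysis depth.
#' @param policy `"drop-with-warning"` or `"error"`.
#' @return character vector: mapped codes, `NA` for dropped ones.
#' @export
map_to_level <- function(vocab, code, level, policy = c("drop-with-warning", "error")) {
  stopifnot(inherits(vocab, "traj_vocab"), .is_count(level, min = 0L))
  policy <- match.arg(policy)
  code <- normalize_code(code)
  out <- code
  is_tx <- startsWith(code, "TX:") | (!is.na(vocab$kind[code]) & vocab$kind[code] == "treatment")
  todo <- which(!is_tx)
  if (vocab$mode == "ccsr") {
    mapped <- vocab$ccsr_map[code[todo]]
    already <- code[todo] %in% vocab$codes$code
    mapped[already] <- code[todo][already]
    out[todo] <- unname(mapped)
  } else if (vocab$mode == "flat") {
    known <- code[todo] %in% vocab$codes$code
    out[todo][!known] <- NA_character_
  } else {
    depths <- vocab$depth[code[todo]]
    for (j in seq_along(todo)) {
      i <- todo[j]
      d <- depths[j]
      if (is.na(d)) { out[i] <- NA_character_; next }
      c_ <- code[i]
      while (d > level) {
        c_ <- vocab$parent[[c_]]
        d <- d - 1L
      }
      out[i] <- c_
    }
  }
  miss <- is.na(out)
  if (any(miss)) {
    if (policy == "error") .fail("unknown code(s): ", paste(unique(code[miss]), collapse = ", "))
    vocab$counters$unmapped <- vocab$counters$unmapped + sum(miss)
    warning(sum(miss), " code(s) not found in vocabulary; dropped", call. = FALSE)
  }
  out
}

#' Number of codes dropped so far because they were missing from the vocabulary
#' @param vocab a `traj_vocab`.
#' @return integer counter.
#' @export
vocab_unmapped_count <- function(vocab) vocab$counters$unmapped

#' Is a code excluded from the analysis?
#'
#' True iff the code or any of its hierarchy ancestors is in the exclusion
#' set, unless the code itself is whitelisted (whitelist wins).
#'
#' @param vocab a `traj_vocab`.
#' @param code character vector of codes.
#' @return logical vector.
#' @export
is_excluded <- function(vocab, code) {
  stopifnot(inherits(vocab, "traj_vocab"))
  code <- normalize_code(code)
  vapply(code, function(c_) {
    if (c_ %in% vocab$whitelist) return(FALSE)
    if (!(c_ %in% names(vocab$parent))) return(c_ %in% vocab$excluded)
    any(.ancestry(vocab, c_) %in% vocab$excluded)
  }, logical(1), USE.NAMES = FALSE)
}

#' Human-readable names for codes
#' @param vocab a `traj_vocab`.
#' @param code character vector of (analysis-level) codes.
#' @return character vector of labels; unknown codes label as themselves.
#' @export
code_name <- function(vocab, code) {
  code <- normalize_code(code)
  nm <- unname(vocab$name[code])
  ifelse(is.na(nm), code, nm)
}
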
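# Fixture builders shared across test files. Everything is generated in code;
# no stored data.

# tiny ICD-10-like hierarchy as a flat TSV on disk
write_tiny_hierarchy <- function(path = tempfile(fileext = ".tsv")) {
  writeLines(c(
    "code\tparent\tdepth\tname",
    "II\t\t\tNeoplasms",
    "C64-C68\tII\t\tUrinary tract cancers",
    "C67\tC64-C68\t\tBladder cancer",
    "C67.2\tC67\t\tBladder cancer lateral wall",
    "C67.9\tC67\t\tBladder cancer unspecified",
    "X\t\t\tRespiratory",
    "J40-J47\tX\t\tChronic lower respiratory",
    "J44\tJ40-J47\t\tCOPD",
    "XV\t\t\tPregnancy",
    "O10-O16\tXV\t\tHypertensive disorders in pregnancy",
    "O10\tO10-O16\t\tPre-existing hypertension in pregnancy",
    "XXI\t\t\tHealth status factors",
    "Z80-Z99\tXXI\t\tPersonal history",
    "Z85\tZ80-Z99\t\tHistory of malignant neoplasm",
    "Z85.5\tZ85\t\tHistory of urinary tract neoplasm",
    "Z85.51\tZ85.5\t\tHistory of bladder cancer"
  ), path)
  path
}

# the same hierarchy as ClaML-style XML
write_tiny_claml <- function(path = tempfile(fileext = ".xml")) {
  writeLines(c(
    "<ClaML>",
    '  <Class code="II" kind="chapter"><Rubric kind="preferred"><Label>Neoplasms</Label></Rubric></Class>',
    '  <Class code="C64-C68" kind="block"><SuperClass code="II"/><Rubric kind="preferred"><Label>Urinary tract cancers</Label></Rubric></Class>',
    '  <Class code="C67" kind="category"><SuperClass code="C64-C68"/><Rubric kind="preferred"><Label>Bladder cancer</Label></Rubric></Class>',
    '  <Class code="C67.2" kind="subcategory"><SuperClass code="C67"/><Rubric kind="preferred"><Label>Lateral wall</Label></Rubric></Class>',
    "</ClaML>"
  ), path)
  path
}

# assemble a cohort from in-memory patient / event data frames
make_cohort <- function(patients, events, vocab = NULL, level = 0L,
                        n_age_groups = 1L, anchor_codes = "C67") {
  if (is.null(vocab)) {
    codes <- unique(trajmine::normalize_code(events$CODE))
    vocab <- trajmine::vocabulary_from_codes(codes)
  }
  p <- trajmine::read_patient_table(patients)
  co <- trajmine::read_event_table(events, p, vocab, level, anchor_codes = anchor_codes)
  trajmine::assign_age_groups(co, n_age_groups)
}

# quick patient frame: n patients, alternating sex, fixed birth years
patient_frame <- function(n, birth_years = 1950L, sexes = c("M", "F")) {
  data.frame(
    PID = sprintf("P%03d", seq_len(n)),
    SEX = rep_len(sexes, n),
    BIRTH_YEAR = rep_len(birth_years, n),
    TAGS = "",
    stringsAsFactors = FALSE
  )
}

# random small cohort for property tests: each patient gets a random subset
# of `codes` at random dates
random_events <- function(pids, codes, p_code = 0.5,
                          day0 = as.Date("2010-01-01"), span = 2000L) {
  rows <- list()
  for (pid in pids) {
    for (cd in codes) {
      if (stats::runif(1) < p_code) {
        rows[[length(rows) + 1L]] <- data.frame(
          PID = pid, CODE = cd,
          DATE = as.character(day0 + sample.int(span, 1L) - 1L),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  do.call(rbind, rows)
}
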
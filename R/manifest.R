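# Deterministic cohort design: who is in the study, their cytology tier,
# histology/follow-up truth, subtype and cellularity grade. The validation
# design fixes the margins of the reference study design: 105 benign / 65
# malignant, 29 borderline histologies (FA, NIFTP, WDT-UMP), and 72
# adequate-cellularity samples split 17/23/9/23 across TIR2-TIR5.

validation_design <- function() {
  tibble::tribble(
    ~cytology, ~truth,      ~subtype,   ~n, ~n_adequate,
    "TIR2",    "benign",    "HP",       28L, 15L,
    "TIR2",    "benign",    "HT",        3L,  1L,
    "TIR2",    "benign",    "other",     2L,  1L,
    "TIR3",    "benign",    "HP",       36L, 12L,
    "TIR3",    "benign",    "HT",        5L,  1L,
    "TIR3",    "benign",    "FA",       18L,  5L,
    "TIR3",    "benign",    "NIFTP",     7L,  2L,
    "TIR3",    "benign",    "WDT-UMP",   2L,  1L,
    "TIR3",    "malignant", "PTC",       9L,  2L,
    "TIR4",    "benign",    "HP",        2L,  0L,
    "TIR4",    "benign",    "NIFTP",     1L,  0L,
    "TIR4",    "benign",    "WDT-UMP",   1L,  0L,
    "TIR4",    "malignant", "PTC",      13L,  9L,
    "TIR4",    "malignant", "MTC",       2L,  0L,
    "TIR5",    "malignant", "PTC",      38L, 21L,
    "TIR5",    "malignant", "MTC",       3L,  2L
  )
}

# Scale the default validation design to arbitrary per-cytology totals with
# largest-remainder apportionment; with the default counts (33/77/19/41) the
# design is reproduced exactly.
scale_validation_design <- function(counts) {
  des <- validation_design()
  out <- lapply(names(counts), function(cy) {
    d <- des[des$cytology == cy, ]
    n_new <- alloc_largest_remainder(d$n, counts[[cy]])
    adq <- alloc_largest_remainder(d$n_adequate + 1e-9, min(sum(d$n_adequate), counts[[cy]]))
    if (identical(as.integer(counts[[cy]]), sum(d$n))) {
      n_new <- d$n
      adq <- d$n_adequate
    }
    d$n <- pmin(n_new, counts[[cy]])
    d$n_adequate <- pmin(adq, d$n)
    d
  })
  dplyr::bind_rows(out)
}

expand_design <- function(design, id_prefix, set_name) {
  rows <- purrr::pmap(design, function(cytology, truth, subtype, n, n_adequate) {
    if (n == 0L) return(NULL)
    grade <- rep("poor", n)
    if (n_adequate > 0) {
      grade[seq_len(n_adequate)] <- rep(c("good", "optimal"), length.out = n_adequate)
    }
    tibble::tibble(set = set_name, cytology = cytology, truth = truth,
                   subtype = subtype, cellularity = grade)
  })
  out <- dplyr::bind_rows(rows)
  if (!nrow(out)) {
    return(tibble::tibble(sample_id = character(), set = character(),
                          cytology = character(), truth = character(),
                          subtype = character(), cellularity = character()))
  }
  out$sample_id <- sprintf("%s%03d", id_prefix, seq_len(nrow(out)))
  dplyr::select(out, "sample_id", "set", "cytology", "truth", "subtype",
                "cellularity")
}

#' Build the per-sample cohort manifest implied by a configuration
#'
#' @param config An [cohort_config()] object.
#' @return Tibble with columns `sample_id`, `set`, `cytology`, `truth`,
#'   `subtype`, `cellularity`.
#' @export
design_manifest <- function(config) {
  tr <- tibble::tibble(
    set = "training",
    cytology = c(rep("TIR2", config$n_hp_train + config$n_ht_train),
                 rep("TIR5", config$n_ptc_train)),
    truth = c(rep("benign", config$n_hp_train + config$n_ht_train),
              rep("malignant", config$n_ptc_train)),
    subtype = c(rep("HP", config$n_hp_train), rep("HT", config$n_ht_train),
                rep("PTC", config$n_ptc_train)),
    cellularity = rep_len(c("good", "optimal"),
                          config$n_hp_train + config$n_ht_train +
                            config$n_ptc_train)
  )
  tr$sample_id <- sprintf("TR%03d", seq_len(nrow(tr)))
  tr <- dplyr::select(tr, "sample_id", "set", "cytology", "truth", "subtype",
                      "cellularity")
  va <- expand_design(scale_validation_design(config$validation_cytology),
                      "VA", "validation")
  dplyr::bind_rows(tr, va)
}

# phenotype mixture a nodule carries on its informative pixels
sample_composition <- function(set, truth, subtype, config) {
  if (truth == "malignant") {
    f <- if (set == "training") config$malignant_fraction_train
         else config$malignant_fraction_validation
    comp <- c(PTC = f, HP = 1 - f)
  } else if (subtype %in% c("FA", "NIFTP", "WDT-UMP")) {
    comp <- c(HP = 1 - config$borderline_fraction,
              PTC = config$borderline_fraction)
  } else if (subtype == "HT") {
    comp <- c(HT = 1)
  } else {
    comp <- c(HP = 1)
  }
  comp[comp > 0]
}
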
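# Bundled reference tables from a 19-patient hepatic-resection cohort:
# per-group conductivity summaries, printed conductivity ratios, per-tumor-
# type summaries and per-patient 1 MHz values. Cells that were visibly
# garbled in the source report (decimal point dropped, e.g. "012", "041",
# "043") are stored normalized with typo_normalized = TRUE and the literal
# printed string kept where applicable; nothing is silently corrected.

ref_path <- function(file) {
  p <- system.file("extdata", file, package = "tetracond")
  if (p == "") stop_data("bundled reference table '%s' not found", file)
  p
}

#' Bundled liver-conductivity reference tables
#'
#' Published group-level values from a clinical liver cohort (19 analysed
#' patients; normal, tumor and cirrhotic tissue, in vivo and ex vivo),
#' against which the package's analysis operations are checked:
#' \describe{
#'   \item{`reference_group_summary()`}{mean +/- SD conductivity (S/m) per
#'     (tissue class, state) at 3, 30, 300, 607 and 1000 kHz.}
#'   \item{`reference_ratio_table()`}{the six printed ratios of group means
#'     per frequency (Tin/Nin, Tin/Tex, Tex/Nin, Tin/Cin, Tex/Cin, Nin/Cin).}
#'   \item{`reference_tumor_type_summary()`}{tumor-tissue summaries split by
#'     tumor type (CCA / HCC / MET), in vivo and ex vivo; single-case cells
#'     carry no SD.}
#'   \item{`reference_patient_1mhz()`}{per-patient conductivities at 1 MHz
#'     with disease, tumor size and cirrhosis status; missing cells are
#'     technically invalid measurements, kept as NA.}
#' }
#' Cells whose printed form had an obvious dropped decimal point are stored
#' normalized and flagged `typo_normalized`.
#'
#' @return A data frame (see above).
#' @export
reference_group_summary <- function() {
  utils::read.csv(ref_path("liver_group_summary.csv"),
                  colClasses = c(printed_mean = "character"))
}

#' @rdname reference_group_summary
#' @export
reference_ratio_table <- function() {
  utils::read.csv(ref_path("liver_ratio_printed.csv"))
}

#' @rdname reference_group_summary
#' @export
reference_tumor_type_summary <- function() {
  utils::read.csv(ref_path("liver_tumor_type_summary.csv"))
}

#' @rdname reference_group_summary
#' @export
reference_patient_1mhz <- function() {
  utils::read.csv(ref_path("patient_conductivity_1mhz.csv"))
}

#' Tissue groups from the per-patient 1 MHz reference values
#'
#' Extracts the four comparison groups used in the omnibus rank test at
#' 1 MHz: in vivo normal (non-cirrhotic patients only), ex vivo normal,
#' in vivo tumor and ex vivo tumor. Missing (technically invalid) cells are
#' dropped.
#'
#' @return named list of four numeric vectors of conductivities, S/m.
#' @export
reference_patient_1mhz_groups <- function() {
  df <- reference_patient_1mhz()
  list(
    in_vivo_normal = df$sigma_in_vivo_normal[!df$cirrhotic &
                                             !is.na(df$sigma_in_vivo_normal)],
    ex_vivo_normal = df$sigma_ex_vivo_normal[!is.na(df$sigma_ex_vivo_normal)],
    in_vivo_tumor = df$sigma_in_vivo_tumor[!is.na(df$sigma_in_vivo_tumor)],
    ex_vivo_tumor = df$sigma_ex_vivo_tumor[!is.na(df$sigma_ex_vivo_tumor)]
  )
}
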
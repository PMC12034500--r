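#' Synthetic stand-in attribute table for the 21 Veracruz cycads
#'
#' The raw attribute table underlying the published CPI for the Veracruz
#' cycad flora is not redistributable here, so this function returns a
#' clearly-labelled SYNTHETIC stand-in: the species list and genus
#' composition (13 *Ceratozamia*, 6 *Zamia*, 2 *Dioon*) are real, and every
#' cell that the published account fixes is honoured -- *Z. vazquezii* with
#' 2 localities and ~91% habitat loss, *Z. inermis* with a single locality,
#' *C. dominguezii* with 5 localities and ~87% habitat loss, *C. mexicana*
#' with ~82% loss, severe categories for the eight high-risk species and
#' mild ones for *D. edule* and *Z. loddigesii*. All remaining cells are
#' plausible genus-typical values fixed once when the package was written;
#' they are NOT the published measurements, so quantities computed from this
#' table approximate, but do not reproduce, the published ones.
#'
#' @return A validated species attribute tibble (21 rows).
#' @export
#' @examples
#' build_scored_table(cycad_attributes_synthetic())[, c("species_name", "cpi")]
cycad_attributes_synthetic <- function() {
  tab <- tibble::tribble(
    ~species_name,               ~genus,        ~iucn_category, ~endemic, ~nom059_category, ~n_localities, ~eoo_km2, ~pct_area_in_region, ~pct_habitat_loss, ~pct_outside_pa, ~n_municipalities,
    "Ceratozamia brevifrons",    "Ceratozamia", "EN",           TRUE,     "A",              8L,            1200,     100,                 65,                85,              6L,
    "Ceratozamia decumbens",     "Ceratozamia", "CR",           TRUE,     "P",              3L,            180,      100,                 78,                100,             3L,
    "Ceratozamia delucana",      "Ceratozamia", "VU",           FALSE,    "A",              12L,           6500,     60,                  55,                90,              9L,
    "Ceratozamia dominguezii",   "Ceratozamia", "EN",           FALSE,    "P",              5L,            400,      70,                  87,                100,             2L,
    "Ceratozamia euryphyllidia", "Ceratozamia", "EN",           FALSE,    "P",              6L,            900,      55,                  70,                95,              3L,
    "Ceratozamia fuscoviridis",  "Ceratozamia", "EN",           FALSE,    "A",              7L,            2500,     45,                  72,                88,              5L,
    "Ceratozamia mexicana",      "Ceratozamia", "EN",           TRUE,     "A",              10L,           3000,     100,                 82,                92,              8L,
    "Ceratozamia miqueliana",    "Ceratozamia", "EN",           FALSE,    "A",              9L,            2800,     50,                  68,                90,              4L,
    "Ceratozamia morettii",      "Ceratozamia", "EN",           TRUE,     "P",              4L,            350,      100,                 80,                100,             3L,
    "Ceratozamia robusta",       "Ceratozamia", "VU",           FALSE,    "A",              15L,           30000,    20,                  60,                85,              7L,
    "Ceratozamia subroseophylla","Ceratozamia", "CR",           TRUE,     "P",              3L,            250,      100,                 75,                100,             2L,
    "Ceratozamia tenuis",        "Ceratozamia", "EN",           TRUE,     "P",              4L,            300,      100,                 83,                100,             4L,
    "Ceratozamia totonacorum",   "Ceratozamia", "VU",           TRUE,     "A",              6L,            1800,     100,                 62,                95,              5L,
    "Dioon edule",               "Dioon",       "NT",           FALSE,    "A",              35L,           60000,    35,                  40,                80,              28L,
    "Dioon spinulosum",          "Dioon",       "VU",           FALSE,    "A",              14L,           12000,    30,                  52,                75,              10L,
    "Zamia furfuracea",          "Zamia",       "EN",           TRUE,     "P",              5L,            600,      100,                 58,                90,              4L,
    "Zamia inermis",             "Zamia",       "CR",           TRUE,     "P",              1L,            50,       100,                 88,                100,             1L,
    "Zamia loddigesii",          "Zamia",       "NT",           FALSE,    "A",              30L,           80000,    25,                  45,                85,              22L,
    "Zamia purpurea",            "Zamia",       "EN",           FALSE,    "P",              4L,            500,      40,                  74,                100,             3L,
    "Zamia splendens",           "Zamia",       "VU",           FALSE,    "A",              8L,            4000,     35,                  66,                92,              6L,
    "Zamia vazquezii",           "Zamia",       "CR",           TRUE,     "P",              2L,            80,       100,                 91,                100,             2L
  )
  validate_species_table(tab)
}

#' Reconstructed knowledge-shortfall table for the Veracruz cycads
#'
#' Unlike the attribute table, the knowledge-status table can be
#' reconstructed from published summary statistics, which pin down: 52% of
#' the 21 species (11) with individual counts, 95% (20, all but
#' *C. dominguezii*) with GenBank accessions, all 21 with at least ten
#' scholarly studies, 38% (8) with population-ecology information, 52% (11)
#' with a known pollinator; *C. dominguezii* as the only species with the
#' minimum score 1, and *Z. inermis* and *C. miqueliana* as the only species
#' with the maximum 5. The assignment of the remaining TRUE cells among
#' species is not uniquely determined by those statistics; the choices here
#' follow the better-studied species but are a reconstruction, not the
#' published table. All marginal shares and the extreme rows are exact.
#'
#' @return A knowledge tibble (21 rows) with `shortfall_score`.
#' @export
#' @examples
#' shortfall_summary(cycad_knowledge_reconstructed())
cycad_knowledge_reconstructed <- function() {
  ind <- c("Ceratozamia decumbens", "Ceratozamia mexicana",
           "Ceratozamia miqueliana", "Ceratozamia morettii",
           "Ceratozamia tenuis", "Dioon edule", "Dioon spinulosum",
           "Zamia furfuracea", "Zamia inermis", "Zamia loddigesii",
           "Zamia vazquezii")
  pe <- c("Zamia inermis", "Ceratozamia miqueliana", "Zamia vazquezii",
          "Ceratozamia decumbens", "Ceratozamia delucana", "Zamia splendens",
          "Ceratozamia tenuis", "Ceratozamia morettii")
  pol <- c("Ceratozamia euryphyllidia", "Ceratozamia mexicana",
           "Ceratozamia miqueliana", "Ceratozamia robusta", "Dioon edule",
           "Dioon spinulosum", "Zamia furfuracea", "Zamia inermis",
           "Zamia loddigesii", "Zamia purpurea", "Zamia splendens")
  sp <- cycad_attributes_synthetic()$species_name
  out <- tibble::tibble(
    species_name = sp,
    has_individual_count = sp %in% ind,
    has_genbank = sp != "Ceratozamia dominguezii",
    has_studies = TRUE,
    has_popecol = sp %in% pe,
    has_pollinator = sp %in% pol
  )
  out$shortfall_score <- shortfall_score(out)
  out
}
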
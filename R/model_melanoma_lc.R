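# The bundled synthetic melanoma-Langerhans-cell model.

#' Load the synthetic reduced melanoma-LC signalling model
#'
#' A 44-node / 50-edge qualitative network coupling a melanoma cell to an
#' epidermal Langerhans cell (LC). It is *synthetic*: a reduced model written
#' for this package from well-established signalling biology, not a
#' transcription of any published curated model. It encodes:
#' \itemize{
#'   \item the MAPK cascade (RTK/RAS/BRAF/MEK/ERK) with a `BRAF_V600E` input
#'     that short-circuits it, and an Ets-1 switch that requires full MAPK
#'     output;
#'   \item TNF-alpha transcription requiring Sp1, Ets-1 and cJUN together, and
#'     an autocrine positive feedback loop TNF -> TNFR -> JNK -> cJUN -> TNF
#'     whose receptor saturates at half-maximal ligand. In MITF-high
#'     backgrounds the loop is bistable (off = small-tumour state, on =
#'     TNF-producing state); in MITF-low backgrounds cJUN is constitutive and
#'     the loop locks on;
#'   \item PI3K/AKT (released by PTEN loss), NFkB survival signalling,
#'     p53/MDM2 and the CyclinD/CDK4/E2F cell-cycle axis feeding the
#'     `Proliferation` and `Apoptosis` behaviour nodes;
#'   \item the LC compartment: TGF-beta -> TBR -> SMAD3 -> Id2 retains LCs in
#'     the epidermis (`Residency_LC`, range 0-4), opposed by melanoma TNF via
#'     `TNFR_LC` and by IL-1beta relayed through keratinocytes (`KC_signal`);
#'     PI3K/AKT and MAPK branches feed `Survival_LC` and `Proliferation_LC`.
#' }
#' Five backgrounds clamp the input nodes: `healthy` plus four
#' BRAF^V600E CDKN2A-null tumours crossing PTEN status with MITF-high/low. The
#' drug table covers MAPK inhibitors (dabrafenib and its alias vemurafenib,
#' trametinib, ulixertinib), TGF-beta-pathway inhibitors (a TGF-beta-1
#' antibody, SIS3, GW788388), the Id2 inhibitor AGX51, and melanoma-directed
#' drugs (BMS345541, copanlisib, capivasertib, idasanutlin, abemaciclib,
#' HLM006474). A small experiment table records the qualitative behaviour the
#' model is built to show.
#'
#' @return a list with elements `network` (`qn_network`), `backgrounds`
#'   (named list of `qn_background`), `drugs` (named list of `qn_drug`) and
#'   `experiments` (list of `qn_experiment`).
#' @examples
#' \donttest{
#' m <- qn_melanoma_lc()
#' b <- qn_stable_bounds(qn_apply(m$network, m$backgrounds$healthy))
#' qn_reported_level(b, "Residency_LC")
#' }
#' @export
qn_melanoma_lc <- function() {
  dir <- system.file("extdata", "melanoma_lc_synthetic", package = "qualnet",
                     mustWork = TRUE)
  network <- qn_read_model_tables(file.path(dir, "nodes.csv"),
                                  file.path(dir, "edges.csv"),
                                  file.path(dir, "functions.csv"),
                                  name = "synthetic melanoma-LC model")
  backgrounds <- qn_read_backgrounds(file.path(dir, "backgrounds.csv"), network)
  drugs <- qn_read_drugs(file.path(dir, "drugs.csv"), network)
  experiments <- qn_read_experiments(file.path(dir, "experiments.csv"),
                                     backgrounds, drugs)
  list(network = network, backgrounds = backgrounds, drugs = drugs,
       experiments = experiments)
}
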
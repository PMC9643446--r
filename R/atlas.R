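# Desikan-Killiany cortical parcellation (34 patches per hemisphere) and the
# lobe assignment used for region-level summaries: frontal, parietal,
# temporal, occipital, cingulate and insular, per hemisphere.

.dk_base <- c(
  "bankssts", "caudalanteriorcingulate", "caudalmiddlefrontal", "cuneus",
  "entorhinal", "frontalpole", "fusiform", "inferiorparietal",
  "inferiortemporal", "insula", "isthmuscingulate", "lateraloccipital",
  "lateralorbitofrontal", "lingual", "medialorbitofrontal", "middletemporal",
  "paracentral", "parahippocampal", "parsopercularis", "parsorbitalis",
  "parstriangularis", "pericalcarine", "postcentral", "posteriorcingulate",
  "precentral", "precuneus", "rostralanteriorcingulate",
  "rostralmiddlefrontal", "superiorfrontal", "superiorparietal",
  "superiortemporal", "supramarginal", "temporalpole", "transversetemporal")

.dk_region <- c(
  bankssts = "temporal", caudalanteriorcingulate = "cingulate",
  caudalmiddlefrontal = "frontal", cuneus = "occipital",
  entorhinal = "temporal", frontalpole = "frontal", fusiform = "temporal",
  inferiorparietal = "parietal", inferiortemporal = "temporal",
  insula = "insular", isthmuscingulate = "cingulate",
  lateraloccipital = "occipital", lateralorbitofrontal = "frontal",
  lingual = "occipital", medialorbitofrontal = "frontal",
  middletemporal = "temporal", paracentral = "frontal",
  parahippocampal = "temporal", parsopercularis = "frontal",
  parsorbitalis = "frontal", parstriangularis = "frontal",
  pericalcarine = "occipital", postcentral = "parietal",
  posteriorcingulate = "cingulate", precentral = "frontal",
  precuneus = "parietal", rostralanteriorcingulate = "cingulate",
  rostralmiddlefrontal = "frontal", superiorfrontal = "frontal",
  superiorparietal = "parietal", superiortemporal = "temporal",
  supramarginal = "parietal", temporalpole = "temporal",
  transversetemporal = "temporal")

#' Desikan-Killiany patch labels
#'
#' The 68 cortical patch labels (34 per hemisphere, `-lh`/`-rh` suffix) in
#' the canonical order used throughout the package.
#' @return character vector of length 68
#' @export
dk_labels <- function() {
  c(paste0(.dk_base, "-lh"), paste0(.dk_base, "-rh"))
}

#' Region scheme mapping patches to lobe-by-hemisphere nodes
#'
#' Maps each cortical patch to one of six regions (frontal, parietal,
#' temporal, occipital, cingulate, insular) crossed with hemisphere, giving
#' up to 12 region nodes such as `frontal-lh`. The insular node contains a
#' single patch per hemisphere.
#'
#' @param patch_labels character vector of patch labels with `-lh`/`-rh`
#'   suffixes; defaults to the full 68-patch parcellation.
#' @return object of class `region_scheme`: a data.frame with columns
#'   `patch`, `base`, `region`, `hemi`, `node`, plus attribute `nodes`
#'   (the ordered region-node labels present).
#' @export
region_scheme <- function(patch_labels = dk_labels()) {
  base <- sub("-(lh|rh)$", "", patch_labels)
  hemi <- sub("^.*-(lh|rh)$", "\\1", patch_labels)
  bad <- !(base %in% .dk_base) | !(hemi %in% c("lh", "rh"))
  if (any(bad)) {
    stop("unknown patch label(s): ", paste(patch_labels[bad], collapse = ", "))
  }
  if (anyDuplicated(patch_labels)) stop("duplicate patch labels")
  region <- unname(.dk_region[base])
  node <- paste0(region, "-", hemi)
  region_order <- c("frontal", "parietal", "temporal", "occipital",
                    "cingulate", "insular")
  nodes <- as.vector(t(outer(region_order, c("lh", "rh"), paste, sep = "-")))
  nodes <- nodes[nodes %in% node]
  out <- data.frame(patch = patch_labels, base = base, region = region,
                    hemi = hemi, node = node, stringsAsFactors = FALSE)
  attr(out, "nodes") <- nodes
  class(out) <- c("region_scheme", "data.frame")
  out
}

#' Homotopic left/right patch pairs of a region scheme
#' @param scheme a [region_scheme()]
#' @return data.frame with columns `base`, `lh`, `rh`, `region`
#' @export
homotopic_pairs <- function(scheme) {
  lh <- scheme[scheme$hemi == "lh", ]
  rh <- scheme[scheme$hemi == "rh", ]
  common <- intersect(lh$base, rh$base)
  if (length(common) == 0) stop("no homotopic pairs in scheme")
  unpaired <- setdiff(union(lh$base, rh$base), common)
  if (length(unpaired) > 0) {
    stop("unpaired patch(es): ", paste(unpaired, collapse = ", "))
  }
  data.frame(base = common,
             lh = paste0(common, "-lh"),
             rh = paste0(common, "-rh"),
             region = unname(.dk_region[common]),
             stringsAsFactors = FALSE)
}

# An even-sized subset of patches that preserves homotopy and spans all six
# regions; used by the synthetic generator for reduced configurations.
dk_subset <- function(n_patches) {
  if (n_patches %% 2 != 0 || n_patches < 2 || n_patches > 68) {
    stop("n_patches must be an even number in [2, 68]")
  }
  preferred <- c("superiorfrontal", "superiorparietal", "superiortemporal",
                 "lateraloccipital", "posteriorcingulate", "insula",
                 "rostralmiddlefrontal", "inferiorparietal", "middletemporal",
                 "cuneus", "caudalanteriorcingulate", "precentral",
                 "supramarginal", "fusiform", "lingual", "precuneus",
                 "parsopercularis")
  bases <- unique(c(preferred, .dk_base))[seq_len(n_patches / 2)]
  c(paste0(bases, "-lh"), paste0(bases, "-rh"))
}
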
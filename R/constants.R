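# Fixed anatomical inventories and parameter-path display names.
# The state layout here must stay in lockstep with src/pbtk_ode.c.

# organ order fixed: lung first (in series between venous and arterial
# pools), then liver and kidney (eliminating organs), then the rest.
ORGAN_NAMES <- c(
  "lung", "liver", "kidney", "muscle", "skin", "adipose", "brain", "heart",
  "gonads", "bone", "spleen", "stomach_wall", "small_intestine_wall",
  "large_intestine_wall", "rest"
)

# organs whose venous outflow drains into the portal vein
PORTAL_ORGANS <- c("spleen", "stomach_wall", "small_intestine_wall",
                   "large_intestine_wall")

LUMEN_SEGMENTS <- c("stomach", "duodenum", "upper_jejunum", "lower_jejunum",
                    "upper_ileum", "lower_ileum", "caecum", "colon")
SI_SEGMENTS <- c("duodenum", "upper_jejunum", "lower_jejunum",
                 "upper_ileum", "lower_ileum")
LI_SEGMENTS <- c("caecum", "colon")

# pipe-delimited path display names
ORGAN_DISPLAY <- c(
  lung = "Lung", liver = "Liver", kidney = "Kidney", muscle = "Muscle",
  skin = "Skin", adipose = "Adipose", brain = "Brain", heart = "Heart",
  gonads = "Gonads", bone = "Bone", spleen = "Spleen",
  stomach_wall = "Stomach", small_intestine_wall = "SmallIntestine",
  large_intestine_wall = "LargeIntestine", rest = "Rest"
)

LUMEN_DISPLAY <- c(
  stomach = "Stomach", duodenum = "Duodenum", upper_jejunum = "UpperJejunum",
  lower_jejunum = "LowerJejunum", upper_ileum = "UpperIleum",
  lower_ileum = "LowerIleum", caecum = "Caecum", colon = "Colon"
)

COMPOSITION_DISPLAY <- c(f_lipid = "Vf (lipids)", f_protein = "Vf (proteins)",
                         f_water = "Vf (water)")

# state vector layout (1-based R indices)
STATE_NAMES <- c(
  ORGAN_NAMES, "venous_blood", "arterial_blood", "portal_vein",
  paste0("lumen_", LUMEN_SEGMENTS), "metabolized", "urine", "faeces"
)
N_STATES <- length(STATE_NAMES) # 29

IDX_ORGANS <- seq_along(ORGAN_NAMES)
IDX_VEN <- 16L
IDX_ART <- 17L
IDX_POR <- 18L
IDX_LUMEN <- 18L + seq_along(LUMEN_SEGMENTS)
IDX_MET <- 27L
IDX_URN <- 28L
IDX_FAE <- 29L

# special perturbation path for the administered dose (never part of
# model$parameter_paths; compound/protocol fields are not physiology)
DOSE_PATH <- "Application|Dose"
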
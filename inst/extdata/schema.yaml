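# Column map for curated GAG/aggregation entry tables: file header -> the
# canonical column name used by the package (see gag_table_schema()). The
# bundled table already uses canonical headers; the extra aliases below show
# how a transcription with verbose headers can be mapped at load time.
columns:
  protein: protein
  protein_length: protein_length
  protein_net_charge: protein_net_charge
  lys_arg_count: lys_arg_count
  folding_status: folding_status
  disease_related: disease_related
  gag: gag
  sulfates_per_disaccharide: sulfates_per_disaccharide
  charges_per_disaccharide: charges_per_disaccharide
  uronic_acid: uronic_acid
  sulfation_position: sulfation_position
  gag_mw: gag_mw
  solute_molarity: solute_molarity
  protein_conc: protein_conc
  gag_conc: gag_conc
  protein_gag_molar_ratio: protein_gag_molar_ratio
  pH: pH
  temperature: temperature
  buffer: buffer
  t_half_no_gag: t_half_no_gag
  t_half_with_gag: t_half_with_gag
  time_unit: time_unit
  G: G
  source: source
  # aliases
  "sulfates per disaccharide": sulfates_per_disaccharide
  "charges per disaccharide": charges_per_disaccharide
  "solute molarity (mM)": solute_molarity
  "protein:GAG molar ratio": protein_gag_molar_ratio
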
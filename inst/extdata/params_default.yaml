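schema_version: 1.0
species:
  rpc:
    id: rpc
    role: self_replicator
    n_monomers: 7336.14600000000064028
    monomer_kind: aa
    k_rate: 20.26000000000000156
    mass_da: ~
    localization: cytoplasm
    footprint_nm2: ~
    provenance: calibrated
  rp:
    id: rp
    role: polymerase
    n_monomers: 3407.0
    monomer_kind: aa
    k_rate: 85.0
    mass_da: ~
    localization: cytoplasm
    footprint_nm2: ~
    provenance: specific
  rc:
    id: rc
    role: polymerase
    n_monomers: 4536.0
    monomer_kind: aa
    k_rate: 5000.0
    mass_da: ~
    localization: cytoplasm
    footprint_nm2: ~
    provenance: calibrated
  lpe:
    id: lpe
    role: enzyme
    n_monomers: 300.0
    monomer_kind: aa
    k_rate: 100.0
    mass_da: ~
    localization: cytoplasm
    footprint_nm2: ~
    provenance: generic
  enz:
    id: enz
    role: enzyme
    n_monomers: 300.0
    monomer_kind: aa
    k_rate: 100.0
    mass_da: ~
    localization: cytoplasm
    footprint_nm2: ~
    provenance: calibrated
  etc:
    id: etc
    role: membrane_protein
    n_monomers: 24892.20075861350051127
    monomer_kind: aa
    k_rate: 300.0
    mass_da: ~
    localization: membrane
    footprint_nm2: 131.06845548629499376
    provenance: calibrated
  tp:
    id: tp
    role: membrane_protein
    n_monomers: 500.0
    monomer_kind: aa
    k_rate: 100.0
    mass_da: ~
    localization: membrane
    footprint_nm2: 318.65633647501198311
    provenance: calibrated
  rrna:
    id: rrna
    role: rna
    n_monomers: 4566.0
    monomer_kind: nt
    k_rate: .na.real
    mass_da: ~
    localization: cytoplasm
    footprint_nm2: ~
    provenance: specific
  trna:
    id: trna
    role: rna
    n_monomers: 76.0
    monomer_kind: nt
    k_rate: .na.real
    mass_da: ~
    localization: cytoplasm
    footprint_nm2: ~
    provenance: specific
  mrna:
    id: mrna
    role: rna
    n_monomers: 900.0
    monomer_kind: nt
    k_rate: .na.real
    mass_da: ~
    localization: cytoplasm
    footprint_nm2: ~
    provenance: generic
  lip:
    id: lip
    role: lipid
    n_monomers: 1.0
    monomer_kind: lipid_precursor
    k_rate: .na.real
    mass_da: 750.0
    localization: membrane
    footprint_nm2: 0.5
    provenance: calibrated
  dna:
    id: dna
    role: genome
    n_monomers: 9280000.0
    monomer_kind: dnt
    k_rate: .na.real
    mass_da: ~
    localization: cytoplasm
    footprint_nm2: ~
    provenance: specific
pathways:
  PW1:
    id: PW1
    length_reactions: 100.0
    enzyme: enz
    product_monomer: metabolic_intermediate
    atp_per_reaction: 0.0212917328218593
  PW2:
    id: PW2
    length_reactions: 200.0
    enzyme: enz
    product_monomer: aa
    atp_per_reaction: 0.0212917328218593
  PW3:
    id: PW3
    length_reactions: 443.40129327764600475
    enzyme: enz
    product_monomer: dnt
    atp_per_reaction: 0.0212917328218593
  PW4:
    id: PW4
    length_reactions: 150.0
    enzyme: enz
    product_monomer: nt
    atp_per_reaction: 0.0212917328218593
  PW5:
    id: PW5
    length_reactions: 61.56917078573619762
    enzyme: enz
    product_monomer: lipid_precursor
    atp_per_reaction: 0.0212917328218593
geometry:
  shape_mode: fixed_aspect
  aspect_ratio: 2.39999999999999991
  radius_um: 0.34999999999999998
  area_per_lipid_nm2: 0.5
  leaflets: 2.0
  water_mass_fraction: 0.69999999999999996
  density_g_per_cm3: 1.10000000000000009
energy:
  atp_per_aa_polymerized: 4.20000000000000018
  atp_per_nt_polymerized: 2.39999999999999991
  atp_per_dnt_polymerized: 1.28354713792666009
  atp_per_lipid: 1.0
  atp_per_transport: 1.0
  substrates_per_monomer: 1.0
couplings:
  trna_per_ribosome: 8.0
  mrna_nt_per_ribosome: 2516.73098700699028996
  rc_per_genome: 2.0
  rrna_per_ribosome: 1.0
  genome_copies: 1.0
monomer_mass_da:
  aa: 110.0
  nt: 324.0
  dnt: 222.74457822477100422
source_note: canonical defaults; n_rpc, n_enz, l_PW2, mrna_nt_per_ribosome and the
  membrane/energy/DNA sector are calibrated against the canonical operating points
  of the model family; remaining values reference-organism derived
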
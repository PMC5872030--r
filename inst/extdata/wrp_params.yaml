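# Water-retention-pond (WRP) bloom-harvesting case study.
# Only published point values appear here; everything downstream is
# recomputed by the package.
scenario: "WRP bloom, May 2014"

water:                      # physicochemistry during the bloom event
  temperature: 18.1         # deg C
  pH: 7.01
  dissolved_oxygen: 9.86    # mg/L
  conductivity: 302.1       # uS/cm
  salinity: 0.17            # PSU
  dry_weight: 0.13          # g/L
  chlorophyll_a: 443.23     # ug/L
  F: 0.00                   # ions, mg/L
  Cl: 26.49
  NO2: 9.72
  SO4: 6.00
  Br: 0.00
  NO3: 2.59
  PO4: 6.11
  Na: 16.85
  NH4: 0.48
  K: 4.02
  Mg: 9.15
  Ca: 37.42

harvesting:
  dose_mg_per_L: {max: 5, submax: 1.25}       # chitosan operating doses
  efficiency_pct: {max: 91.2, submax: 75.3}   # 10-min flotation efficiencies

composition:                # constituent contents, ug per mg dry biomass
  lipid: 103.7
  phosphate: 9.02
  protein: 325.45

volumes_m3: {low: 5000, high: 10000}   # photic-zone volume range

scaleup:
  batch_volume_L: 24000
  specific_air_rate_mL_per_min_per_L: 1
  operating_pressure_bar_g: 3
  compressor_rated_flow_cfm: 7.1
  derating_fraction: 0.25
  treat_time_min: 30
  fill_time_min: 48
  drain_time_min: 48

costs:
  lake_volume_L: 7500000
  tariff_per_kWh: 0.15      # GBP
  flocculant: {name: chitosan, dose_mg_per_L: 5, price_per_kg: 30}
  items:
    - {name: compressor, capex: 200, opex_per_batch: 0.83, duty_min: 30,
       power_kW: 1.1}       # per-batch OPEX is the published figure
    - {name: rotameter, capex: 60, opex_per_batch: 0, duty_min: 30}
    - {name: fluidic_oscillator, capex: 100, opex_per_batch: 0, duty_min: 30}
    - {name: eFLOAT_tank, capex: [210, 210, 1000], opex_per_batch: 0,
       duty_min: 0}         # 2 diffusers + tank shell
    - {name: pumps, capex: 1000, duty_min: 96, power_kW: 0.32}
    - {name: skimmer, capex: 1000, duty_min: 30, power_kW: 16}

solar:
  load_kW: 1.5
  panel_rating_W: 250
  area_per_panel_m2: 1.5

reference:                  # published values the run is checked against
  stock_low_kg: 650
  lipid_max_high_kg: 123
  phosphate_max_high_kg: 10.69
  protein_max_low_kg: 192.93
  protein_submax_low_kg: 159.29
  air_demand_L_per_min: 24
  derated_flow_L_per_min: 50
  batch_cycle_min: 126
  pump_opex_per_batch: 0.077
  skimmer_opex_per_batch: 1.20
  chitosan_full_cost: 1125
  total_opex_bound: 2000
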
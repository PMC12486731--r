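# Default costing configuration: group delivery of the prevention programme,
# health-service perspective, NOK. Durations in hours.
resources:
  child_session_duration: 1.0
  parent_session_duration: 1.5
  prep_per_session: 1.0
  mfs_review_hours: 8.0
  supervision_hours_per_leader: 4.0
  recruitment_hours_per_leader: 2.0
  group_leaders: 2
  group_size: 5
unit_costs:
  loaded_hourly_rate: 529.0      # school health nurse wage x 1.4 social costs
  social_cost_multiplier: 1.4
  workbooks_low_parental: 1345.0 # per group, brochure-only parental arm
  workbooks_high_parental: 2540.0
  mfs_app: 225.0                 # per group, feedback strategies only
  supervision_fee: 1000.0        # flat supervisor fee per group
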
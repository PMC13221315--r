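domains:
- id: planning
  label: Service planning
  indicators:
  - code: W1.1
    label: O&M plan
  - code: W1.2
    label: Clear roles and responsibilities
  - code: W1.3
    label: Dedicated budget line
  - code: W1.4
    label: Preventive maintenance schedule
- id: design
  label: Facility design standards
  indicators:
  - code: W2.1
    label: Sanitation technology
  - code: W2.2
    label: Safe containment of excreta
  - code: W2.3
    label: Facility accessibility for people with disability
  - code: W2.4
    label: Sex segregation
  - code: W2.5
    label: Privacy
  - code: W2.6
    label: MHM facility availability
  - code: W2.7
    label: Handwashing facilities
  - code: W2.8
    label: Pupil to stance ratio
- id: resources
  label: Resource management
  indicators:
  - code: W3.1
    label: Trained personnel
  - code: W3.2
    label: Reliable water supply
  - code: W3.3
    label: Budget line implementation
  - code: W3.4
    label: Material-use tracking system
- id: delivery
  label: Service delivery
  indicators:
  - code: W4.1
    label: Facility availability
  - code: W4.2
    label: General facility accessibility
  - code: W4.3
    label: Facility functionality
  - code: W4.4
    label: Toilet cleanliness
  - code: W4.5
    label: Toilet consumables at point of use
  - code: W4.6
    label: MHM materials availability
  - code: W4.7
    label: Safe disposal of solid waste
  - code: W4.8
    label: Safe excreta disposal
- id: governance
  label: Governance
  indicators:
  - code: W5.1
    label: Hygiene promotion activities
  - code: W5.2
    label: Formal school management structures
  - code: W5.3
    label: Internal and external stakeholder engagement
  - code: W5.4
    label: Enforcement
- id: monitoring
  label: M&E
  indicators:
  - code: W6.1
    label: Use of structured M&E tools
  - code: W6.2
    label: Multiple stakeholder monitoring
  - code: W6.3
    label: Making informed decisions from monitoring data
  - code: W6.4
    label: M&E training for personnel
  - code: W6.5
    label: Escalation process for unresolved issues
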
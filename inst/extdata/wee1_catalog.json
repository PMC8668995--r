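{"sites":[{"name":"g-loop-E309","ref_pos":309,"expected":"E","category":"g-loop"},{"name":"atp-K328","ref_pos":328,"expected":"K","category":"atp-contact"},{"name":"gatekeeper","ref_pos":376,"expected":"N","category":"gatekeeper"},{"name":"atp-C379","ref_pos":379,"expected":"C","category":"atp-contact"},{"name":"catalytic-D","ref_pos":426,"expected":"D","category":"catalytic"},{"name":"atp-K428","ref_pos":428,"expected":"K","category":"atp-contact"},{"name":"atp-N431","ref_pos":431,"expected":"N","category":"atp-contact"},{"name":"dfg-D","ref_pos":463,"expected":"D","category":"activation"},{"name":"dfg-2","ref_pos":464,"expected":"LF","category":"activation"},{"name":"dfg-G","ref_pos":465,"expected":"G","category":"activation"},{"name":"egd-E","ref_pos":477,"expected":"E","category":"egd"},{"name":"egd-G","ref_pos":478,"expected":"G","category":"egd"},{"name":"egd-D","ref_pos":479,"expected":"D","category":"egd"},{"name":"docking-R481","ref_pos":481,"expected":"R","category":"docking"},{"name":"docking-R518","ref_pos":518,"expected":"R","category":"docking"}],"patterns":[{"name":"catalytic-segment","pattern":"IVHxDLKPxNIx","anchor_start":422,"anchor_end":433},{"name":"egd-motif","pattern":"EGD","anchor_start":477,"anchor_end":479}],"segments":[{"name":"g-loop","start":303,"end":312},{"name":"atp-binding","start":374,"end":381},{"name":"catalytic","start":422,"end":433},{"name":"activation","start":461,"end":482}]}
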
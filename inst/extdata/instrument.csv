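"item_id","area","scale_min","scale_max","description"
"communication_01","communication",1,5,"spontaneous eye contact"
"communication_02","communication",1,5,"speech understanding"
"communication_03","communication",1,5,"reacting to name"
"communication_04","communication",1,5,"indicating"
"communication_05","communication",1,5,"imitating adults or other children"
"communication_06","communication",1,5,"adequate gestures"
"communication_07","communication",1,5,"alternative communication skills"
"communication_08","communication",1,5,"ability to use speech"
"communication_09","communication",1,5,"greeting and saying good bye"
"communication_10","communication",1,5,"asking and answering questions"
"communication_11","communication",1,5,"spontaneously starting to communicate"
"communication_12","communication",1,5,"expressing physiological needs"
"communication_13","communication",1,5,"expressing other needs and preferences"
"communication_14","communication",1,5,"maintaining a conversation"
"fine_motor_01","fine_motor",1,5,"holding pencil"
"fine_motor_02","fine_motor",1,5,"colouring"
"fine_motor_03","fine_motor",1,5,"tracing a drawing"
"fine_motor_04","fine_motor",1,5,"cutting"
"fine_motor_05","fine_motor",1,5,"grabbing small objects"
"fine_motor_06","fine_motor",1,5,"building a tower of blocks"
"fine_motor_07","fine_motor",1,5,"putting beads onto a necklace"
"fine_motor_08","fine_motor",1,5,"fastening buttons"
"gross_motor_01","gross_motor",1,5,"standing on one leg"
"gross_motor_02","gross_motor",1,5,"jumping on one or both legs"
"gross_motor_03","gross_motor",1,5,"squats"
"gross_motor_04","gross_motor",1,5,"climbing stairs"
"gross_motor_05","gross_motor",1,5,"throwing a ball at a target"
"gross_motor_06","gross_motor",1,5,"kicking a ball"
"gross_motor_07","gross_motor",1,5,"running"
"gross_motor_08","gross_motor",1,5,"riding a bike"
"gross_motor_09","gross_motor",1,5,"climbing a chair or sofa"
"following_instructions_01","following_instructions",1,5,"simple instructions"
"following_instructions_02","following_instructions",1,5,"complex instructions"
"self_reliance_01","self_reliance",1,5,"dressing"
"self_reliance_02","self_reliance",1,5,"eating"
"self_reliance_03","self_reliance",1,5,"cleaning up"
"self_reliance_04","self_reliance",1,5,"using a toilet"
"self_reliance_05","self_reliance",1,5,"washing hands"
"self_reliance_06","self_reliance",1,5,"tooth brushing"
"social_emotional_01","social_emotional",1,5,"reciprocal smile"
"social_emotional_02","social_emotional",1,5,"contacting adults or other children"
"social_emotional_03","social_emotional",1,5,"sharing with adults or other children"
"social_emotional_04","social_emotional",1,5,"recognizing others' emotions"
"social_emotional_05","social_emotional",1,5,"understanding own emotions"
"social_emotional_06","social_emotional",1,5,"joining other children spontaneously"
"social_emotional_07","social_emotional",1,5,"asking for help"
"social_emotional_08","social_emotional",1,5,"empathic reactions to others' emotions"
"social_emotional_09","social_emotional",1,5,"taking part in a symbolic play"
"stereotypical_01","stereotypical",1,5,"motor stereotypes"
"stereotypical_02","stereotypical",1,5,"echolalia"
"stereotypical_03","stereotypical",1,5,"routine behaviours"
"stereotypical_04","stereotypical",1,5,"reaction to change in routine"
"stereotypical_05","stereotypical",1,5,"reaction to novelty"
"stimulation_reaction_01","stimulation_reaction",1,5,"reaction to motion stimuli"
"stimulation_reaction_02","stimulation_reaction",1,5,"reaction to visual stimuli"
"stimulation_reaction_03","stimulation_reaction",1,5,"reaction to auditory stimuli"
"stimulation_reaction_04","stimulation_reaction",1,5,"reaction to taste stimuli"
"stimulation_reaction_05","stimulation_reaction",1,5,"reaction to smell stimuli"
"stimulation_reaction_06","stimulation_reaction",1,5,"reaction to touch stimuli"
"attention_01","attention",1,5,"following others' indication"
"attention_02","attention",1,5,"indicating attention"
"attention_03","attention",1,5,"focusing on a given task"
"attention_04","attention",1,5,"focusing on a talking therapist"
"attention_05","attention",1,5,"moving from one activity to another"
"challenging_01","challenging",1,5,"aggressive or autoaggressive behaviours"
"challenging_02","challenging",1,5,"crying"
"challenging_03","challenging",1,5,"screaming"
"challenging_04","challenging",1,5,"apathy"
"challenging_05","challenging",1,5,"inadequate laugh"
"challenging_06","challenging",1,5,"escaping"
"challenging_07","challenging",1,5,"emotional lability"
"challenging_08","challenging",1,5,"not accepting refusals"
"challenging_09","challenging",1,5,"stimulating behaviours"
"challenging_10","challenging",1,5,"problems with calming down"
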
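fine_class_id	superclass
n_airliner	airplane
n_warplane	airplane
n_biplane	airplane
n_brown_bear	bear
n_polar_bear	bear
n_mountain_bike	bicycle
n_tandem_bicycle	bicycle
n_robin	bird
n_magpie	bird
n_goldfinch	bird
n_canoe	boat
n_speedboat	boat
n_sports_car	car
n_jeep	car
n_minivan	car
n_beagle	dog
n_collie	dog
n_husky	dog
n_african_elephant	elephant
n_indian_elephant	elephant
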
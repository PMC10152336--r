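message_id,category,bct_tag,stratum,green_space_type,allowed_weekdays,allowed_slots,text
step_low_01,STEP,feedback_on_performance,LOW,ANY,Mon|Tue|Wed|Thu|Fri|Sat|Sun,morning|evening,"So far you have taken <number> steps today, <name>. There is still plenty of day left, so how about a short walk to get going?"
step_low_02,STEP,feedback_on_performance,LOW,ANY,Mon|Tue|Wed|Thu|Fri|Sat|Sun,morning|evening,"So far you have taken <number> steps today, <name>. There is still plenty of day left, so how about a short walk to get going? Every little walk counts, so keep moving at your own pace today."
step_mid_01,STEP,feedback_on_performance,MID,ANY,Mon|Tue|Wed|Thu|Fri|Sat|Sun,morning|evening,"So far you have taken <number> steps today, <name>. Well done! You can be proud of yourself."
step_mid_02,STEP,feedback_on_performance,MID,ANY,Mon|Tue|Wed|Thu|Fri|Sat|Sun,morning|evening,"So far you have taken <number> steps today, <name>. Well done! You can be proud of yourself. Fresh air and a steady pace make the day feel a lot lighter."
step_high_01,STEP,feedback_on_performance,HIGH,ANY,Mon|Tue|Wed|Thu|Fri|Sat|Sun,morning|evening,"Fantastic, <name>! You have already taken <number> steps today. Keep this up and your daily goal is well within reach."
step_high_02,STEP,feedback_on_performance,HIGH,ANY,Mon|Tue|Wed|Thu|Fri|Sat|Sun,morning|evening,"Fantastic, <name>! You have already taken <number> steps today. Keep this up and your daily goal is well within reach. Small steps add up quickly when you keep at it every single day."
geo_park_01,GEO,provide_instruction,ANY,park,Mon|Tue|Wed|Thu|Fri|Sat|Sun,morning|evening,Do you want to get some extra steps in today? You are close to a <green_space_type> where you can enjoy a nice walk.
geo_park_02,GEO,provide_instruction,ANY,park,Mon|Tue|Wed|Thu|Fri|Sat|Sun,morning|evening,"Do you want to get some extra steps in today? You are close to a <green_space_type> where you can enjoy a nice walk. Every little walk counts, so keep moving at your own pace today."
geo_forest_01,GEO,provide_instruction,ANY,forest,Mon|Tue|Wed|Thu|Fri|Sat|Sun,morning|evening,Do you want to get some extra steps in today? You are close to a <green_space_type> where you can enjoy a nice walk.
geo_forest_02,GEO,provide_instruction,ANY,forest,Mon|Tue|Wed|Thu|Fri|Sat|Sun,morning|evening,Do you want to get some extra steps in today? You are close to a <green_space_type> where you can enjoy a nice walk. A short stroll outside can clear your head and lift your mood.
geo_walking_trail_01,GEO,provide_instruction,ANY,walking_trail,Mon|Tue|Wed|Thu|Fri|Sat|Sun,morning|evening,Do you want to get some extra steps in today? You are close to a <green_space_type> where you can enjoy a nice walk.
geo_walking_trail_02,GEO,provide_instruction,ANY,walking_trail,Mon|Tue|Wed|Thu|Fri|Sat|Sun,morning|evening,"Do you want to get some extra steps in today? You are close to a <green_space_type> where you can enjoy a nice walk. Every little walk counts, so keep moving at your own pace today."
bct_action_planning_01,BCT,action_planning,ANY,ANY,Mon|Tue|Wed|Thu|Fri|Sat|Sun,morning|evening,Good preparation is half the battle won! Plan and write down when and where you will go for a walk in the coming days.
bct_action_planning_02,BCT,action_planning,ANY,ANY,Mon|Tue|Wed|Thu|Fri|Sat|Sun,morning|evening,Good preparation is half the battle won! Plan and write down when and where you will go for a walk in the coming days. Small steps add up quickly when you keep at it every single day.
bct_reward_01,BCT,reward,ANY,ANY,Mon|Tue|Wed|Thu|Fri|Sat|Sun,morning|evening,"Hey <name>, keep up the good work! Try to keep walking every day. You can do it."
bct_reward_02,BCT,reward,ANY,ANY,Mon|Tue|Wed|Thu|Fri|Sat|Sun,morning|evening,"Hey <name>, keep up the good work! Try to keep walking every day. You can do it. Small steps add up quickly when you keep at it every single day."
bct_social_comparison_01,BCT,social_comparison,ANY,ANY,Mon|Tue|Wed|Thu|Fri|Sat|Sun,morning|evening,"Hi <name>, here's a little fact: last week, 73% of walkers in the programme took enough steps every day!"
bct_social_comparison_02,BCT,social_comparison,ANY,ANY,Mon|Tue|Wed|Thu|Fri|Sat|Sun,morning|evening,"Hi <name>, here's a little fact: last week, 73% of walkers in the programme took enough steps every day! A short stroll outside can clear your head and lift your mood."
bct_consequences_01,BCT,consequences,ANY,ANY,Mon|Tue|Wed|Thu|Fri|Sat|Sun,morning|evening,Did you know that walking can help relieve stress? Walking makes your brain release chemicals that stimulate relaxation and improve your mood.
bct_consequences_02,BCT,consequences,ANY,ANY,Mon|Tue|Wed|Thu|Fri|Sat|Sun,morning|evening,Did you know that walking can help relieve stress? Walking makes your brain release chemicals that stimulate relaxation and improve your mood. A short stroll outside can clear your head and lift your mood.
bct_barrier_identification_01,BCT,barrier_identification,ANY,ANY,Mon|Tue|Wed|Thu|Fri|Sat|Sun,morning|evening,"No time to go for a walk? Get your steps in throughout the day by taking the stairs, getting off the bus a stop earlier, or parking further away."
bct_barrier_identification_02,BCT,barrier_identification,ANY,ANY,Mon|Tue|Wed|Thu|Fri|Sat|Sun,morning|evening,"No time to go for a walk? Get your steps in throughout the day by taking the stairs, getting off the bus a stop earlier, or parking further away. Small steps add up quickly when you keep at it every single day."
bct_social_support_01,BCT,social_support,ANY,ANY,Mon|Tue|Wed|Thu|Fri|Sat|Sun,morning|evening,"Hey <name>, have you told your friends or family about your walking goals? That way, they can support or join you for a walk!"
bct_social_support_02,BCT,social_support,ANY,ANY,Mon|Tue|Wed|Thu|Fri|Sat|Sun,morning|evening,"Hey <name>, have you told your friends or family about your walking goals? That way, they can support or join you for a walk! Small steps add up quickly when you keep at it every single day."
bct_social_approval_01,BCT,social_approval,ANY,ANY,Mon|Tue|Wed|Thu|Fri|Sat|Sun,morning|evening,"Good morning <name>. If you manage to keep walking regularly, your friends and family will surely be proud of you."
bct_social_approval_02,BCT,social_approval,ANY,ANY,Mon|Tue|Wed|Thu|Fri|Sat|Sun,morning|evening,"Good morning <name>. If you manage to keep walking regularly, your friends and family will surely be proud of you. Every little walk counts, so keep moving at your own pace today."
bct_goal_setting_01,BCT,goal_setting,ANY,ANY,Mon|Tue|Wed|Thu|Fri|Sat|Sun,morning|evening,"What's your new goal, <name>? Set yourself an achievable walking goal for this week."
bct_goal_setting_02,BCT,goal_setting,ANY,ANY,Mon|Tue|Wed|Thu|Fri|Sat|Sun,morning|evening,"What's your new goal, <name>? Set yourself an achievable walking goal for this week. Every little walk counts, so keep moving at your own pace today."
bct_self_monitoring_01,BCT,self_monitoring,ANY,ANY,Mon|Tue|Wed|Thu|Fri|Sat|Sun,morning|evening,Curious to know how many steps you've already taken today? Try to keep track by checking the step counter every day.
bct_self_monitoring_02,BCT,self_monitoring,ANY,ANY,Mon|Tue|Wed|Thu|Fri|Sat|Sun,morning|evening,"Curious to know how many steps you've already taken today? Try to keep track by checking the step counter every day. Every little walk counts, so keep moving at your own pace today."
bct_review_goals_01,BCT,review_goals,ANY,ANY,Mon|Tue|Wed|Thu|Fri|Sat|Sun,morning|evening,"Did you achieve this week's walking goal, <name>? If so, good job! If not, try to think of a new goal for next week."
bct_review_goals_02,BCT,review_goals,ANY,ANY,Mon|Tue|Wed|Thu|Fri|Sat|Sun,morning|evening,"Did you achieve this week's walking goal, <name>? If so, good job! If not, try to think of a new goal for next week. A short stroll outside can clear your head and lift your mood."
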